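# Event-driven shift simulation and the five-component objective.

test_that("an empty shift has all-zero metrics", {
  sc <- generate_ed_scenario(ed_config(rates_per_hour = 0), seed = 1)
  ms <- simulate_shift("fcfswu", sc)
  expect_equal(ms$objective, 0)
  expect_true(all(ms$components == 0))
  expect_equal(ms$pre_count, 0L)
})

test_that("a lone patient follows the closed path arrival -> discharge", {
  # one patient, one CE=1 physician, immediate seating, with lab + second exam
  sc <- make_ed_scenario(
    data.frame(arrival_min = 0, tt1_min = 20, needs_second = TRUE,
               tt2_min = 10, lt_min = 15),
    physicians = ed_physicians(1L), shift_min = 240)
  ms <- simulate_shift("fcfswu", sc)
  expect_equal(ms$per_patient$los_min, 20 + 15 + 10)
  expect_equal(ms$per_patient$wt1_min, 0)
  expect_equal(ms$per_patient$wt2_min, 0)

  phys <- data.frame(id = "c1", seniority = "intern", specialty = NA, ce = 2L,
                     stringsAsFactors = FALSE)
  sc2 <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 20),
                          physicians = phys, shift_min = 240)
  ms2 <- simulate_shift("fcfswu", sc2)
  expect_equal(ms2$per_patient$los_min, 2 * 20) # CE doubles the treatment time
})

test_that("the crowding integral equals total in-department time", {
  w <- ed_weights()
  for (s in c(3, 9)) {
    sc <- generate_ed_scenario(ed_config(), seed = s)
    ms <- simulate_shift("fcfswu", sc, w, seed = s)
    expect_equal(sum(ms$kappa) * sc$slot_min, sum(ms$per_patient$los_min),
                 tolerance = 1e-9)
    expect_equal(unname(ms$components[["crowd"]]), sum(ms$kappa) * sc$slot_min)
  }
})

test_that("identical seeds and policies reproduce the trace exactly", {
  sc <- generate_ed_scenario(ed_config(), seed = 17)
  m <- comparator(ed_schema(sc$cfg$injuries)$length, hidden = 8,
                  schema_id = ed_schema(sc$cfg$injuries)$id, seed = 2)
  a <- simulate_shift("lba", sc, seed = 5, model = m)
  b <- simulate_shift("lba", sc, seed = 5, model = m)
  expect_identical(a$per_patient, b$per_patient)
  expect_identical(a$components, b$components)
})

test_that("the objective is linear in its weights", {
  sc <- generate_ed_scenario(ed_config(), seed = 4)
  w <- ed_weights()
  ms <- simulate_shift("fcfswu", sc, w, seed = 1)
  a2 <- w$alpha
  a2[["los"]] <- 2 * a2[["los"]]
  w2 <- ed_weights(alpha = a2)
  expect_equal(ed_objective(ms, w2) - ed_objective(ms, w),
               unname(w$alpha[["los"]] * ms$components[["los"]]),
               tolerance = 1e-9)
  expect_equal(ed_objective(ms, ed_weights(alpha = c(risk = 0, wait = 0, los = 0,
                                                     crowd = 0, preempt = 0))),
               ms$terminal)
})

test_that("simulator and solver accounting agree on an offline schedule", {
  w <- ed_weights()
  for (s in c(2, 5)) {
    sc <- generate_ed_scenario(tiny_ed_config(), seed = s)
    if (nrow(sc$patients) == 0) next
    sol <- solve_offline(build_offline_milp(sc, w))
    expect_equal(ed_objective(sol, w), sol$objective, tolerance = 1e-6)
    expect_equal(sol$objective, sol$solver_objective, tolerance = 1e-6)
  }
})

test_that("preempted treatments resume with remaining time preserved", {
  # urgent arrival forces FCFSwU to interrupt the attending specialist
  sc <- make_ed_scenario(
    data.frame(arrival_min = c(0, 10), tt1_min = c(30, 10),
               severity = c(4, 1), injury = "internal"),
    physicians = ed_physicians(1L), shift_min = 240)
  ms <- simulate_shift("fcfswu", sc)
  expect_gte(ms$pre_count, 1L)
  expect_true(all(ms$per_patient$completed))
  # work-preserving: total LOS of patient 1 = own treatment + interruption gap
  expect_equal(ms$per_patient$los_min[2], 10) # urgent seated instantly
  expect_equal(ms$per_patient$los_min[1], 30 + 10)
})
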