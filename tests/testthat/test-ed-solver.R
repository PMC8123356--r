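# Exact offline solver vs the enumeration oracle, derived quantities, and
# the independent constraint checker.

test_that("a lone patient is treated immediately and contiguously", {
  sc <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 10),
                         physicians = ed_physicians(1L))
  sol <- solve_offline(build_offline_milp(sc))
  expect_equal(sol$st[1, 1], 0L) # starts at slot 0
  expect_equal(sol$et[1, 1], 2L) # TT = 2 slots, CE = 1
  expect_equal(sol$wt[1, 1], 0)
  expect_equal(sol$pc[1, 1], 0L)
  expect_equal(sum(sol$y), 2)
})

test_that("a CE = 2 physician occupies CE * TT slots", {
  phys <- data.frame(id = "c1", seniority = "intern", specialty = NA,
                     ce = 2L, stringsAsFactors = FALSE)
  sc <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 10),
                         physicians = phys)
  sol <- solve_offline(build_offline_milp(sc))
  expect_equal(sum(sol$y), 4) # 2 nominal slots * CE 2
  expect_equal(sol$et[1, 1] - sol$st[1, 1], 4L)
  expect_equal(sol$pc[1, 1], 0L) # contiguous treatment: no restarts
})

test_that("solver and enumeration oracle agree exactly on a tiny battery", {
  w <- ed_weights()
  checked <- 0L
  for (s in 1:15) {
    sc <- generate_ed_scenario(tiny_ed_config(), seed = s)
    if (nrow(sc$patients) == 0) next
    model <- build_offline_milp(sc, w)
    sol <- solve_offline(model)
    oracle <- brute_force_schedule(sc, w, max_nodes = 3e6)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-9)
    chk <- check_schedule(sol, model)
    expect_true(chk$ok)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("the checker flags tampered schedules", {
  sc <- make_ed_scenario(data.frame(arrival_min = c(0, 0), tt1_min = c(10, 10)))
  model <- build_offline_milp(sc)
  sol <- solve_offline(model)
  bad <- sol
  slot_on <- which(bad$y, arr.ind = TRUE)[1, ]
  bad$y[slot_on[1], slot_on[2], slot_on[3], slot_on[4]] <- FALSE
  chk <- check_schedule(bad, model)
  expect_false(chk$ok)
  expect_gt(length(chk$violations), 0L)
})

test_that("an extra identical physician never worsens the optimum", {
  w <- ed_weights()
  for (s in c(2, 6)) {
    sc <- generate_ed_scenario(tiny_ed_config(), seed = s)
    if (nrow(sc$patients) == 0) next
    obj1 <- solve_offline(build_offline_milp(sc, w))$objective
    sc2 <- sc
    extra <- sc$physicians[1, ]
    extra$id <- "c_extra"
    sc2$physicians <- rbind(sc$physicians, extra)
    obj2 <- solve_offline(build_offline_milp(sc2, w))$objective
    expect_lte(obj2, obj1 + 1e-9)
  }
})

test_that("infeasible horizons are reported, oversized oracles refuse", {
  sc <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 40),
                         physicians = ed_physicians(1L))
  expect_error(solve_offline(build_offline_milp(sc, horizon = 4L)), "infeasible")
  sc2 <- generate_ed_scenario(ed_training_config(), seed = 2)
  expect_error(brute_force_schedule(sc2, max_nodes = 10), "refuses")
})

test_that("an empty scenario solves to objective zero", {
  sc <- generate_ed_scenario(ed_config(rates_per_hour = 0), seed = 1)
  sol <- solve_offline(build_offline_milp(sc))
  expect_equal(sol$objective, 0)
  expect_equal(brute_force_schedule(sc)$objective, 0)
})
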