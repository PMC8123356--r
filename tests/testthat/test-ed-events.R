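# Decision-event extraction from offline-optimal schedules.

test_that("one patient with two physicians yields one arrival event and 2 pairs", {
  sc <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 10),
                         physicians = ed_physicians(2L))
  sol <- solve_offline(build_offline_milp(sc))
  evs <- extract_decision_events(sol)
  # arrival event + completion event (the latter has no waiting patient)
  expect_equal(length(evs), 2L)
  arrival_ev <- evs[[1L]]
  expect_equal(nrow(arrival_ev$rejected), 2L) # other physician + wait room
  pr <- suppressWarnings(build_training_pairs(evs))
  expect_equal(n_pairs(pr), 2L)
})

test_that("event count equals arrivals (both stages) plus completions", {
  w <- ed_weights()
  for (s in c(1, 4, 8)) {
    sc <- generate_ed_scenario(tiny_ed_config(), seed = s)
    n <- nrow(sc$patients)
    if (n == 0) next
    sol <- solve_offline(build_offline_milp(sc, w))
    evs <- extract_decision_events(sol)
    n2 <- sum(sc$patients$needs_second)
    expect_equal(length(evs), 2L * (n + n2))
  }
})

test_that("an immediately seated arrival is never recorded as a wait-room choice", {
  sc <- make_ed_scenario(data.frame(arrival_min = 0, tt1_min = 10),
                         physicians = ed_physicians(2L))
  sol <- solve_offline(build_offline_milp(sc))
  evs <- extract_decision_events(sol)
  sch <- ed_schema(sc$cfg$injuries)
  phys_cols <- seq(sch$length - length(sc$cfg$injuries) - 2L, sch$length)
  for (ev in evs) {
    if (!length(ev$chosen)) next
    expect_gt(sum(abs(ev$chosen[phys_cols])), 0) # physician block populated
  }
})

test_that("chosen features reflect the offline state at the instant", {
  # patient 2 arrives while patient 1 is being treated by the only physician
  sc <- make_ed_scenario(
    data.frame(arrival_min = c(0, 10), tt1_min = c(30, 10),
               severity = c(3, 3)),
    physicians = ed_physicians(1L), shift_min = 200)
  sol <- solve_offline(build_offline_milp(sc))
  evs <- extract_decision_events(sol)
  pr <- suppressWarnings(build_training_pairs(evs))
  expect_gt(n_pairs(pr), 0L)
  # all feature vectors have the schema length
  expect_equal(ncol(pr$preferred), ed_schema(sc$cfg$injuries)$length)
})
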