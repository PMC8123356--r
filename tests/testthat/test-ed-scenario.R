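# Arrival-process and scenario-generator properties.

test_that("a zero rate function yields zero patients", {
  cfg <- ed_config(rates_per_hour = 0)
  sc <- generate_ed_scenario(cfg, seed = 1)
  expect_equal(nrow(sc$patients), 0L)
  expect_length(nhpp_times(function(t) 0, 100, 0), 0L)
})

test_that("homogeneous arrivals match the Poisson mean within 3 s.e.", {
  cfg <- ed_config(rates_per_hour = 6, shift_min = 480)
  counts <- vapply(1:300, function(s) {
    nrow(generate_ed_scenario(cfg, seed = s)$patients)
  }, numeric(1))
  mu <- 6 * 8 # rate * hours
  se <- sqrt(mu / 300)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("heavy flow doubles the expected patient count", {
  normal <- ed_config(flow = 1)
  heavy <- ed_config(flow = 2)
  n1 <- vapply(1:300, function(s) nrow(generate_ed_scenario(normal, seed = s)$patients),
               numeric(1))
  n2 <- vapply(1:300, function(s) nrow(generate_ed_scenario(heavy, seed = 1000 + s)$patients),
               numeric(1))
  se_diff <- sqrt(var(n2) / 300 + 4 * var(n1) / 300)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se_diff)
})

test_that("generation is seed-reproducible and slot-discretised consistently", {
  cfg <- ed_config()
  a <- generate_ed_scenario(cfg, seed = 77)
  b <- generate_ed_scenario(cfg, seed = 77)
  expect_identical(a$patients, b$patients)
  p <- a$patients
  expect_true(all(p$tt1 == ceiling(p$tt1_min / cfg$slot_min)))
  expect_true(all(p$arrival == floor(p$arrival_min / cfg$slot_min)))
  expect_true(all(p$severity %in% 1:5))
  expect_true(all(p$arrival < a$horizon))
  expect_true(all(p$tt2[p$needs_second] > 0))
  expect_true(all(p$tt2[!p$needs_second] == 0))
})

test_that("negative rates and malformed configs are rejected", {
  expect_error(ed_config(rates_per_hour = c(3, -1)), "non-negative")
  expect_error(nhpp_times(function(t) -1, 10, 5), "negative")
  expect_error(ed_config(injury_probs = c(0.5, 0.5)), "length")
})

test_that("scenario JSON round-trips", {
  sc <- generate_ed_scenario(ed_training_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_ed_scenario(sc, path)
  back <- read_ed_scenario(path)
  expect_equal(back$patients$arrival, sc$patients$arrival)
  expect_equal(back$patients$tt1, sc$patients$tt1)
  expect_equal(back$horizon, sc$horizon)
  expect_equal(back$physicians$ce, sc$physicians$ce)
})
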