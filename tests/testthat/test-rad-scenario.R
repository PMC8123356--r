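# Radiology scenario generation, reading times, quantal response, utilities.

test_that("default conditions give 10 readers and 60 studies within the deadline range", {
  sc <- generate_radiology_scenario(rad_config(), seed = 1)
  expect_equal(length(sc$subspec), 10L)
  expect_equal(nrow(sc$studies), 60L)
  expect_true(all(sc$studies$deadline_min >= 30))
  expect_true(all(sc$studies$deadline_min <= 10080))
  expect_true(all(sc$studies$arrival >= 0 & sc$studies$arrival < rad_config()$window_min))
  b <- generate_radiology_scenario(rad_config(), seed = 1)
  expect_identical(sc$studies, b$studies)
})

test_that("a zero rate profile yields no studies", {
  sc <- generate_radiology_scenario(rad_config(rates_per_hour = 0), seed = 1)
  expect_equal(nrow(sc$studies), 0L)
})

test_that("reading time is nominal in-subspecialty and rho-fold outside", {
  cfg <- rad_config()
  expect_equal(reading_time(c("CT|head"), "CT|head", cfg), 3)
  expect_equal(reading_time(c("MRI|chest"), "CT|head", cfg), 9)
  near1 <- rad_config(rho = 1 + 1e-9)
  expect_equal(reading_time(character(0), "CT|head", near1),
               reading_time(c("CT|head"), "CT|head", near1),
               tolerance = 1e-6)
  expect_error(reading_time(c("CT|head"), "PET|tail", cfg), "unknown")
})

test_that("quantal response is a proper softmax", {
  expect_equal(choice_probabilities(rep(1, 4)), rep(0.25, 4))
  expect_equal(choice_probabilities(5), 1)
  p <- choice_probabilities(c(1, 0))
  expect_equal(p[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(sum(choice_probabilities(rnorm(7))), 1, tolerance = 1e-12)
  # monotonicity: raising one utility strictly raises its probability
  u <- c(0.2, 0.5, 0.1)
  expect_gt(choice_probabilities(u + c(0.3, 0, 0))[1], choice_probabilities(u)[1])
  expect_error(choice_probabilities(numeric(0)), "empty")
})

test_that("utilities are normalized selection frequencies", {
  types <- c("A", "B", "C")
  u <- estimate_utilities(list(c(rep("A", 6), rep("B", 4))), types)[[1]]
  expect_equal(unname(u[["A"]]), 0.6)
  expect_equal(unname(u[["C"]]), 0)
  expect_equal(sum(u), 1)
  expect_warning(u0 <- estimate_utilities(list(character(0)), types)[[1]],
                 "empty")
  expect_equal(unname(u0), rep(1 / 3, 3))
})

test_that("estimated frequencies recover known softmax selection rates", {
  set.seed(60)
  types <- paste0("t", 1:6)
  w <- c(1.5, 1, 0.5, 0, 0, -0.5)
  pr <- exp(w) / sum(exp(w))
  n <- 4000
  hist <- sample(types, n, replace = TRUE, prob = pr)
  u <- estimate_utilities(list(hist), types)[[1]]
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(u - pr) < 3 * se + 1e-12))
})

test_that("radiology scenario JSON round-trips", {
  sc <- generate_radiology_scenario(rad_config(n_studies = 8), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_rad_scenario(sc, path)
  back <- read_rad_scenario(path)
  expect_equal(back$studies$due, sc$studies$due)
  expect_equal(back$subspec, sc$subspec)
  expect_equal(back$utility[[1]], sc$utility[[1]])
})
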