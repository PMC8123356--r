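# Decision events -> preference pairs: counting, conservation, IO.

test_that("pair counts equal the number of rejected alternatives", {
  ev1 <- decision_event(c(1, 0), rbind(c(0, 1), c(0, 0), c(1, 1)), "e1")
  expect_equal(n_pairs(build_training_pairs(list(ev1))), 3L)

  evs <- lapply(1:5, function(i) {
    decision_event(rnorm(3), matrix(rnorm(12), 4), paste0("e", i), "s")
  })
  expect_equal(n_pairs(build_training_pairs(evs)), 20L)

  lone <- decision_event(c(1, 2), matrix(numeric(0), 0, 2), "solo")
  expect_equal(n_pairs(build_training_pairs(list(lone))), 0L)
})

test_that("pair-count conservation holds across random event batches", {
  set.seed(14)
  for (rep in 1:10) {
    ks <- sample(0:5, 8, replace = TRUE)
    evs <- lapply(seq_along(ks), function(i) {
      decision_event(rnorm(4), matrix(rnorm(4 * ks[i]), ks[i]), paste0("e", i))
    })
    pr <- build_training_pairs(evs)
    expect_equal(n_pairs(pr), sum(ks))
    expect_equal(as.vector(table(factor(pr$source_event,
                                        levels = paste0("e", seq_along(ks))))),
                 as.integer(ks))
  }
})

test_that("events with no options are skipped with a warning", {
  good <- decision_event(c(1, 0), rbind(c(0, 1)), "ok")
  empty <- decision_event(numeric(0), matrix(numeric(0), 0, 0), "none")
  expect_warning(pr <- build_training_pairs(list(good, empty)), "no options")
  expect_equal(n_pairs(pr), 1L)
})

test_that("mixed schemas are rejected and CSV IO round-trips", {
  a <- decision_event(c(1, 0), rbind(c(0, 1)), "a", schema_id = "s1")
  b <- decision_event(c(1, 0), rbind(c(0, 1)), "b", schema_id = "s2")
  expect_error(build_training_pairs(list(a, b)), "schema")

  set.seed(2)
  pr <- preference_pairs(matrix(rnorm(40), 10), matrix(rnorm(40), 10),
                         schema_id = "s1", source_event = paste0("e", 1:10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_preference_pairs(pr, path)
  back <- read_preference_pairs(path)
  expect_equal(back$preferred, pr$preferred, ignore_attr = TRUE)
  expect_equal(back$rejected, pr$rejected, ignore_attr = TRUE)
  expect_identical(back$schema_id, "s1")
})
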