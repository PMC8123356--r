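# Reading-room simulation: closed paths, accounting audits, pool behaviour.

test_that("a single reader and study give a deterministic closed path", {
  cfg <- rad_config()
  sc <- make_rad_scenario(
    data.frame(M = "CT", B = "head", arrival = 5, deadline_min = 30),
    subspec = list("CT|head"), cfg = cfg)
  r <- simulate_reading_room("naive", sc, seed = 1)
  # idle reader starts at arrival; in-subspecialty read takes 3 minutes
  expect_equal(r$studies$read_start, 5)
  expect_equal(r$studies$read_end, 8)
  expect_equal(r$report$lateness_hours, (8 - 35) / 60)
  r2 <- simulate_reading_room("naive", sc, seed = 1)
  expect_identical(r$studies, r2$studies)
})

test_that("every study is eventually read and losses add up, all policies", {
  sc <- generate_radiology_scenario(rad_config(n_studies = 25), seed = 4)
  m <- comparator(7, hidden = 8, schema_id = "rad/7f", seed = 3)
  for (pol in c("naive", "h", "dnn")) {
    r <- simulate_reading_room(pol, sc, seed = 2,
                               model = if (pol == "dnn") m else NULL)
    expect_true(all(r$studies$status == "done"))
    expect_equal(r$report$total_loss,
                 sum(study_loss((r$studies$read_end - r$studies$due) / 60)),
                 tolerance = 1e-9)
    expect_equal(sum(r$report$bins), 1)
  }
})

test_that("the learned policy's pools never exceed the cap", {
  sc <- generate_radiology_scenario(rad_config(), seed = 6)
  m <- comparator(7, hidden = 8, schema_id = "rad/7f", seed = 5)
  for (k in c(10L, 3L)) {
    r <- simulate_reading_room("dnn", sc, seed = 3, k = k, model = m)
    expect_lte(r$pool_max, k)
    expect_true(all(r$studies$status == "done"))
  }
})

test_that("capped pools run far smaller than naive exposure", {
  sc <- generate_radiology_scenario(rad_config(), seed = 8)
  m <- comparator(7, hidden = 8, schema_id = "rad/7f", seed = 5)
  rn <- simulate_reading_room("naive", sc, seed = 1)
  rd <- simulate_reading_room("dnn", sc, seed = 1, model = m)
  expect_gt(rn$pool_mean, rd$pool_mean)
})

test_that("an empty study stream is handled", {
  sc <- generate_radiology_scenario(rad_config(rates_per_hour = 0), seed = 1)
  r <- simulate_reading_room("naive", sc, seed = 1)
  expect_equal(r$report$total_loss, 0)
  expect_equal(length(r$report$lateness_hours), 0L)
})
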