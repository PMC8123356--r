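# Combined patient-physician feature vector.

test_that("normalised fields and fixed ordering match the schema", {
  sch <- ed_schema(c("internal", "orthopedic", "trauma"))
  expect_equal(sch$length, 13L)
  pat <- list(severity = 3, injury = "orthopedic", remaining_tt_min = 20,
              wait_min = 10, tbar_min = 30)
  phys <- list(seniority = "attending", specialty = "internal",
               status_severity = 0, idle_min = 15)
  v <- featurize_ed_pair(pat, phys, sch)
  expect_length(v, sch$length)
  expect_equal(unname(v[["severity"]]), 3 / 5)
  expect_equal(unname(v[["injury_orthopedic"]]), 1)
  expect_equal(unname(v[["injury_internal"]]), 0)
  expect_equal(unname(v[["time_to_bound_min"]]), 20)
  expect_equal(unname(v[["seniority"]]), 1) # attending = 4/4
  expect_equal(unname(v[["specialty_internal"]]), 1)
  expect_equal(unname(v[["status"]]), 0) # idle
  expect_equal(unname(v[["idle_min"]]), 15)
})

test_that("a busy physician reports the severity of their current patient", {
  sch <- ed_schema(c("internal", "orthopedic"))
  pat <- list(severity = 4, injury = "internal", remaining_tt_min = 15,
              wait_min = 0, tbar_min = 60)
  phys <- list(seniority = "intern", specialty = NA, status_severity = 2,
               idle_min = 0)
  v <- featurize_ed_pair(pat, phys, sch)
  expect_equal(unname(v[["status"]]), 2)
  expect_equal(unname(v[["seniority"]]), 2 / 4)
  expect_equal(unname(sum(v[c("specialty_internal", "specialty_orthopedic")])), 0)
})

test_that("the wait-room dummy zeroes the whole physician block", {
  sch <- ed_schema(c("internal", "orthopedic"))
  pat <- list(severity = 1, injury = "internal", remaining_tt_min = 25,
              wait_min = 5, tbar_min = 0)
  v <- featurize_ed_pair(pat, NULL, sch)
  block <- v[c("seniority", "specialty_internal", "specialty_orthopedic",
               "status", "idle_min")]
  expect_true(all(block == 0))
  expect_equal(unname(v[["severity"]]), 1 / 5)
})

test_that("unknown injury types raise a schema error", {
  sch <- ed_schema(c("internal"))
  pat <- list(severity = 3, injury = "dermatology", remaining_tt_min = 10,
              wait_min = 0, tbar_min = 30)
  expect_error(featurize_ed_pair(pat, NULL, sch), "injury")
})
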