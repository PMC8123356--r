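# Exposure policies: baselines, the learned update rules, featurization.

test_that("the naive policy exposes every pending study to every reader", {
  cfg <- rad_config(n_studies = 12)
  sc <- generate_radiology_scenario(cfg, seed = 2)
  st <- rad_init_state(sc)
  st$now <- max(sc$studies$arrival) + 1
  st$status[] <- 1L
  pools <- naive_expose(st)
  expect_true(all(lengths(pools) == 12L))
  st$status[] <- 3L
  expect_true(all(lengths(naive_expose(st)) == 0L))
})

test_that("the interval heuristic widens exposure in thirds", {
  cfg <- rad_config()
  sc <- make_rad_scenario(
    data.frame(M = "CT", B = "head", arrival = 0, deadline_min = 180),
    subspec = list("CT|head", "CT|chest", "MRI|head"), cfg = cfg)
  st <- rad_init_state(sc)
  st$status[] <- 1L
  # first third [0, 60): exact-type subspecialists only
  st$now <- 30
  expect_equal(lengths(h_expose(st)), c(1L, 0L, 0L))
  # second third [60, 120): readers sharing the modality
  st$now <- 90
  expect_equal(lengths(h_expose(st)), c(1L, 1L, 0L))
  # final third and past the deadline: everyone
  st$now <- 150
  expect_equal(lengths(h_expose(st)), c(1L, 1L, 1L))
  st$now <- 500
  expect_equal(lengths(h_expose(st)), c(1L, 1L, 1L))
})

test_that("the 7-feature encoding matches its schema", {
  cfg <- rad_config()
  sc <- make_rad_scenario(
    data.frame(M = c("CT", "CT"), B = c("head", "chest"),
               arrival = c(0, 0), deadline_min = c(60, 240)),
    subspec = list(c("CT|head"), c("MRI|head")), cfg = cfg)
  st <- rad_init_state(sc)
  st$status[] <- 1L
  st$now <- 10
  v <- featurize_rad_pair(1L, 1L, st)
  expect_length(v, 7L)
  expect_equal(unname(v[["subspec_match"]]), 1)
  expect_equal(unname(v[["pool_subspec_frac"]]), 0) # empty pool
  expect_equal(unname(v[["pool_overdue_count"]]), 0)
  expect_lte(v[["lateness_hours"]], 0) # fresh study
  expect_equal(unname(v[["exposure_count"]]), 0)
  expect_equal(unname(v[["subspec_breadth"]]), 0.5)
  expect_equal(unname(v[["time_left_hours"]]), -v[["lateness_hours"]])

  st$pools[[1]] <- c(1L, 2L)
  v2 <- featurize_rad_pair(2L, 1L, st)
  expect_equal(unname(v2[["pool_subspec_frac"]]), 0.5)
  expect_equal(unname(v2[["exposure_count"]]), 1)
})

test_that("arrival insertion fills under-full pools for every reader", {
  cfg <- rad_config(k = 3)
  sc <- make_rad_scenario(
    data.frame(M = "CT", B = "head", arrival = 0, deadline_min = 60),
    subspec = list("CT|head", "MRI|chest"), cfg = cfg)
  st <- rad_init_state(sc, k = 3)
  st$status[1] <- 1L
  m <- comparator(7, hidden = 4, schema_id = "rad/7f", seed = 1)
  st2 <- dnn_expose_on_arrival(m, st, 1L)
  expect_true(all(vapply(st2$pools, function(p) 1L %in% p, logical(1))))
})

test_that("full pools use the replace-the-worst rule and the orphan guard", {
  cfg <- rad_config(k = 2)
  # studies 1-2 near their deadline; study 3 due in a week
  sc <- make_rad_scenario(
    data.frame(M = "CT", B = "head", arrival = c(0, 0, 0),
               deadline_min = c(30, 40, 10000)),
    subspec = list("CT|head"), cfg = cfg)
  st <- rad_init_state(sc, k = 2)
  st$status[] <- 1L
  st$now <- 20
  st$pools[[1]] <- c(1L, 2L)
  # comparator ranks by current lateness (feature 4): transitive
  m <- linear_feature_comparator(7, idx = 4, slope = 50)
  st2 <- dnn_expose_on_arrival(m, st, 3L)
  # the distant-deadline study loses to the pool's worst member everywhere;
  # the zero-exposure guard still exposes it to exactly one reader
  expect_equal(.subset2(st2, "pools")[[1]][2], 3L)
  expect_equal(lengths(st2$pools)[1], 2L) # cap respected
})

test_that("completion adds the top-ranked unexposed study, respecting the cap", {
  cfg <- rad_config(k = 2)
  sc <- make_rad_scenario(
    data.frame(M = "CT", B = "head", arrival = c(0, 0, 0),
               deadline_min = c(500, 60, 240)),
    subspec = list("CT|head"), cfg = cfg)
  st <- rad_init_state(sc, k = 2)
  st$status[] <- 1L
  st$now <- 10
  m <- linear_feature_comparator(7, idx = 4, slope = 50)
  st2 <- dnn_expose_on_completion(m, st, 1L)
  expect_equal(st2$pools[[1]], 2L) # most urgent unexposed study added
  # under a transitive comparator the added study beats all others pairwise
  for (s in c(1L, 3L)) {
    expect_gte(compare(m, featurize_rad_pair(2L, 1L, st),
                       featurize_rad_pair(s, 1L, st)), 0.5)
  }
  # no unexposed studies -> no-op
  st3 <- st
  st3$pools[[1]] <- c(1L, 2L)
  st3$status[3] <- 3L
  expect_equal(dnn_expose_on_completion(m, st3, 1L)$pools[[1]], c(1L, 2L))
})
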