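# Monte-Carlo tree search over exposure decisions.

# exact oracle: exhaustively enumerate every decision path of the exposure
# process itself (deterministic here: single reader, singleton pools force
# the reader's choice) and take the minimum total loss.
enumerate_min_loss <- function(sc, k = 1, max_candidates = 6L) {
  best <- Inf
  run_with <- function(prefix) {
    idx <- 0L
    probe <- NULL
    decide <- function(st, ep) {
      idx <<- idx + 1L
      if (idx <= length(prefix)) return(prefix[idx])
      probe <<- nrow(ep$actions)
      stop(structure(class = c("epoch_probe", "error", "condition"),
                     list(message = "", call = NULL)))
    }
    st0 <- rad_init_state(sc, k = k)
    final <- tryCatch(
      lbassign:::.rad_advance(st0, sc, decide, max_candidates = max_candidates),
      epoch_probe = function(e) NULL)
    if (is.null(final)) return(list(complete = FALSE, n_actions = probe))
    lat <- (final$read_end - final$due) / 60
    list(complete = TRUE, loss = sum(study_loss(lat)))
  }
  dfs <- function(prefix) {
    r <- run_with(prefix)
    if (r$complete) {
      best <<- min(best, r$loss)
      return(invisible(NULL))
    }
    for (a in seq_len(r$n_actions)) dfs(c(prefix, a))
  }
  dfs(integer(0))
  best
}

test_that("a zero budget is rejected and a lone study is read trivially", {
  cfg <- rad_config(n_readers = 1, n_studies = 1, k = 1)
  sc <- generate_radiology_scenario(cfg, seed = 1)
  expect_error(mcts_search(sc, budget = 0), "budget")
  res <- mcts_search(sc, budget = 5, seed = 1)
  expect_equal(res$reading_order, 1L)
  expect_true(all(res$studies$status == "done"))
})

test_that("the search recovers the exhaustive-minimum reading order", {
  ok <- 0L
  for (s in 1:6) {
    # near-simultaneous arrivals: with one reader the exhaustive-order
    # oracle space then coincides with the reachable exposure orders
    cfg <- rad_config(n_readers = 1, n_studies = 4, k = 1, window_min = 3,
                      deadline_mean_min = 20, subspec_size = 3)
    sc <- generate_radiology_scenario(cfg, seed = s)
    res <- mcts_search(sc, budget = 400, cfg = list(max_candidates = 4),
                       seed = s, k = 1)
    opt <- enumerate_min_loss(sc, k = 1, max_candidates = 4L)
    if (abs(res$total_loss - opt) < 1e-9 * max(1, opt)) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("decision events carry the chosen-versus-rejected structure", {
  cfg <- rad_config(n_readers = 2, n_studies = 5, k = 2, window_min = 10)
  sc <- generate_radiology_scenario(cfg, seed = 3)
  res <- mcts_search(sc, budget = 12, seed = 2)
  expect_gt(length(res$events), 0L)
  for (ev in res$events) {
    expect_length(ev$chosen, 7L)
    expect_gte(nrow(ev$rejected), 1L)
    expect_identical(ev$schema_id, "rad/7f")
  }
  # determinism
  res2 <- mcts_search(sc, budget = 12, seed = 2)
  expect_equal(res$total_loss, res2$total_loss)
  expect_identical(res$reading_order, res2$reading_order)
})

test_that("a larger budget does not hurt on a fixed battery", {
  small <- big <- numeric(4)
  for (s in 1:4) {
    cfg <- rad_config(n_readers = 1, n_studies = 4, k = 1, window_min = 3,
                      deadline_mean_min = 20)
    sc <- generate_radiology_scenario(cfg, seed = 10 + s)
    small[s] <- mcts_search(sc, budget = 2, seed = 1, k = 1)$total_loss
    big[s] <- mcts_search(sc, budget = 300, cfg = list(max_candidates = 4),
                          seed = 1, k = 1)$total_loss
  }
  expect_lte(mean(big), mean(small) * 1.05 + 1e-9)
})
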