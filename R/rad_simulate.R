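# Event-driven reading-room simulation: arrivals trigger exposure updates,
# idle readers draw studies from their pools by quantal response, completions
# trigger exposure updates, until every study is read.

#' Simulate the reading room under an exposure policy
#'
#' Continuous-time event simulation. At each study arrival the policy updates
#' the exposure lists; whenever a reader is idle with a nonempty pool they
#' select one study by quantal response (softmax of their utilities over the
#' pool) and read it for [reading_time()] minutes; the study leaves all pools
#' while being read; completions trigger the policy's completion update. The
#' simulation runs until every study is read (there is no horizon cap), and
#' records each study's signed lateness plus pool-size statistics sampled at
#' every event.
#'
#' Identical `seed`, policy and scenario give an identical trace.
#'
#' @param policy `"naive"`, `"h"` or `"dnn"` (requires `model`).
#' @param scenario a [generate_radiology_scenario()] result.
#' @param seed integer seed (reader choices).
#' @param k pool cap for the `"dnn"` policy (default from the config).
#' @param model a trained [comparator()] on the [rad_schema()] (for
#'   `policy = "dnn"`).
#' @return List of class `rad_sim_result`: `report` (a [lateness_report()]),
#'   `pool_mean`, `pool_sd` (sampled pool sizes), `pool_max`, and the final
#'   `studies` record.
#' @export
simulate_reading_room <- function(policy, scenario, seed = 1L,
                                  k = scenario$cfg$k, model = NULL) {
  stopifnot(inherits(scenario, "rad_scenario"))
  if (identical(policy, "dnn") && is.null(model)) {
    stop_invalid("policy 'dnn' requires a trained comparator model")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  state <- rad_init_state(scenario, k = k)
  n <- state$n
  if (n == 0L) {
    return(structure(list(report = lateness_report(numeric(0)),
                          pool_mean = 0, pool_sd = 0, pool_max = 0,
                          policy = policy, seed = as.integer(seed),
                          k = as.integer(k),
                          studies = as_rad_studies(state)),
                     class = "rad_sim_result"))
  }
  R <- length(state$pools)
  arrivals <- order(state$arrival)
  next_arr <- 1L
  pool_samples <- numeric(0)

  pools_view <- function() {
    switch(policy,
           naive = naive_expose(state),
           h = h_expose(state),
           dnn = lapply(state$pools, function(p) p[state$status[p] == 1L]))
  }

  start_readers <- function() {
    repeat {
      started <- FALSE
      pv <- pools_view()
      for (j in seq_len(R)) {
        if (state$busy_study[j] > 0L) next
        pool <- pv[[j]]
        pool <- pool[state$status[pool] == 1L]
        if (!length(pool)) next
        pr <- choice_probabilities(state$util_s[pool, j])
        sid <- if (length(pool) == 1L) pool else
          pool[sample.int(length(pool), 1L, prob = pr)]
        state$status[sid] <<- 2L
        state$reader[sid] <<- j
        state$read_start[sid] <<- state$now
        rt <- if (state$in_sub[sid, j]) scenario$cfg$nominal_read_min else
          scenario$cfg$rho * scenario$cfg$nominal_read_min
        state$busy_until[j] <<- state$now + rt
        state$busy_study[j] <<- sid
        if (policy == "dnn") {
          state$pools <<- lapply(state$pools, function(p) p[p != sid])
        }
        started <- TRUE
        break
      }
      if (!started) break
    }
  }

  h_boundaries <- function() {
    pend <- which(state$status == 1L)
    if (!length(pend)) return(Inf)
    b <- c(state$arrival[pend] + state$deadline_min[pend] / 3,
           state$arrival[pend] + 2 * state$deadline_min[pend] / 3)
    b <- b[b > state$now + 1e-9]
    if (length(b)) min(b) else Inf
  }

  repeat {
    if (all(state$status == 3L)) break
    t_arr <- if (next_arr <= n) state$arrival[arrivals[next_arr]] else Inf
    t_done <- min(state$busy_until)
    t_bound <- if (policy == "h") h_boundaries() else Inf
    t_next <- min(t_arr, t_done, t_bound)
    if (!is.finite(t_next)) {
      # no scheduled event: pending studies must exist but are orphaned
      # (possible under the learned policy after replacements) -- expose the
      # earliest-due pending study to its best-scoring reader
      pend <- which(state$status == 1L)
      if (!length(pend)) break
      sid <- pend[order(state$due[pend])][1L]
      if (policy == "dnn") {
        sc <- vapply(seq_len(R), function(j) {
          pool <- state$pools[[j]]
          if (length(pool) < state$k) return(1)
          compare(model, featurize_rad_pair(sid, j, state),
                  featurize_rad_pair(pool[length(pool)], j, state))
        }, numeric(1))
        j <- which.max(sc)
        pool <- state$pools[[j]]
        if (length(pool) >= state$k) pool <- pool[-length(pool)]
        state$pools[[j]] <- c(pool, sid)
      }
      start_readers()
      if (all(state$busy_study == 0L) && any(state$status == 1L)) {
        stop_invalid("reading-room simulation stalled; no reader can start")
      }
      next
    }
    state$now <- t_next
    # completions first
    for (j in which(state$busy_until <= t_next + 1e-9)) {
      sid <- state$busy_study[j]
      state$status[sid] <- 3L
      state$read_end[sid] <- state$busy_until[j]
      state$busy_until[j] <- Inf
      state$busy_study[j] <- 0L
      if (policy == "dnn") {
        state <- dnn_expose_on_completion(model, state, j)
      }
    }
    # arrivals at this instant
    while (next_arr <= n &&
           state$arrival[arrivals[next_arr]] <= t_next + 1e-9) {
      sid <- arrivals[next_arr]
      state$status[sid] <- 1L
      next_arr <- next_arr + 1L
      if (policy == "dnn") {
        state <- dnn_expose_on_arrival(model, state, sid)
      }
    }
    pv <- pools_view()
    pool_samples <- c(pool_samples, vapply(pv, length, numeric(1)))
    start_readers()
  }
  lat <- (state$read_end - state$due) / 60
  structure(list(
    report = lateness_report(lat, ids = seq_len(n)),
    pool_mean = if (length(pool_samples)) mean(pool_samples) else 0,
    pool_sd = if (length(pool_samples) > 1) sd(pool_samples) else 0,
    pool_max = if (length(pool_samples)) max(pool_samples) else 0,
    policy = policy, seed = as.integer(seed), k = as.integer(k),
    studies = as_rad_studies(state)
  ), class = "rad_sim_result")
}

#' @export
print.rad_sim_result <- function(x, ...) {
  cat("<rad_sim_result> policy:", x$policy, " total loss:",
      signif(x$report$total_loss, 5),
      " pool mean:", signif(x$pool_mean, 4), "\n")
  invisible(x)
}

#' Write a reading-room simulation report
#'
#' Per-study lateness as CSV plus a JSON summary (binned distribution, total
#' loss, pool-size statistics).
#'
#' @param result a [simulate_reading_room()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_rad_report <- function(result, dir) {
  stopifnot(inherits(result, "rad_sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_study <- result$studies
  per_study$lateness_hours <- (per_study$read_end - per_study$due) / 60
  per_study$loss <- study_loss(per_study$lateness_hours)
  write.csv(per_study, file.path(dir, "per_study_lateness.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    policy = result$policy, k = result$k, seed = result$seed,
    total_loss = result$report$total_loss,
    bins = as.list(result$report$bins),
    pool_mean = result$pool_mean, pool_sd = result$pool_sd,
    pool_max = result$pool_max
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
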