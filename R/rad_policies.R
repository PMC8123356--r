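# Study-to-reader exposure policies: the Naive and interval-based (H)
# baselines and the learned comparator (DNN) policy, plus the 7-feature
# study-reader encoding.
#
# A radiology state is a list with parallel per-study vectors (indexed by
# study id, which equals the row index):
#   now          current time (minutes)
#   n            number of studies
#   arrival, due, deadline_min, type, M   study attributes
#   status       0 unarrived, 1 pending, 2 reading, 3 done
#   reader, read_start, read_end          realised reading record
#   subspec      list per reader: subspecialty type keys
#   utility      list per reader: named utility vector over type keys
#   pools        list per reader: ordered study-id vector (learned policy;
#                the baselines derive pools on the fly)
#   k            pool cap (learned policy only)
#   in_sub       n x R logical matrix: study type in reader's subspecialty
#   util_s       n x R matrix: reader's utility for each study
#   breadth      per study: fraction of readers subspecialised in its type
#   busy_until, busy_study                per-reader reading in progress

#' Initialise a radiology simulation state
#'
#' @param scenario a [generate_radiology_scenario()] result.
#' @param k pool cap (default from the scenario config).
#' @return A radiology state list (see the file header of `rad_policies.R`).
#' @export
rad_init_state <- function(scenario, k = scenario$cfg$k) {
  st <- scenario$studies
  n <- nrow(st)
  R <- length(scenario$subspec)
  in_sub <- matrix(FALSE, max(n, 1L), R)
  util_s <- matrix(0, max(n, 1L), R)
  for (j in seq_len(R)) {
    if (n) {
      in_sub[, j] <- st$type %in% scenario$subspec[[j]]
      util_s[, j] <- scenario$utility[[j]][st$type]
    }
  }
  list(now = 0, n = n,
       arrival = st$arrival, due = st$due, deadline_min = st$deadline_min,
       type = st$type, M = st$M,
       status = rep(0L, n), reader = rep(0L, n),
       read_start = rep(NA_real_, n), read_end = rep(NA_real_, n),
       subspec = scenario$subspec, utility = scenario$utility,
       pools = lapply(seq_len(R), function(j) integer(0)),
       k = as.integer(k), cfg = scenario$cfg,
       in_sub = in_sub, util_s = util_s,
       breadth = if (n) rowMeans(in_sub[seq_len(n), , drop = FALSE]) else numeric(0),
       busy_until = rep(Inf, R), busy_study = rep(0L, R))
}

#' Studies of a radiology state as a data frame
#' @param state a radiology state.
#' @return Data frame with one row per study including the reading record.
#' @export
as_rad_studies <- function(state) {
  data.frame(id = seq_len(state$n), type = state$type,
             arrival = state$arrival, deadline_min = state$deadline_min,
             due = state$due,
             status = c("unarrived", "pending", "reading", "done")[state$status + 1L],
             reader = state$reader, read_start = state$read_start,
             read_end = state$read_end, stringsAsFactors = FALSE)
}

.exposure_count <- function(state, sid) {
  sum(vapply(state$pools, function(p) sid %in% p, logical(1)))
}

#' Radiology feature schema (7 features per study-reader pair)
#' @return A list of class `rad_schema`.
#' @export
rad_schema <- function() {
  structure(list(
    id = "rad/7f",
    length = 7L,
    feature_names = c("subspec_match", "pool_subspec_frac", "pool_overdue_count",
                      "lateness_hours", "subspec_breadth", "time_left_hours",
                      "exposure_count")
  ), class = "rad_schema")
}

#' Featurize a study-reader pair
#'
#' Exactly seven features. Reader side: whether the study lies in the
#' reader's subspecialty, the fraction of the reader's current pool within
#' their subspecialty, and the number of past-deadline studies in their pool.
#' Study side: the study's current (signed) lateness in hours, how broadly
#' the study is specialised (fraction of readers holding its type in their
#' subspecialty), time left until the deadline in hours, and the number of
#' readers the study is currently exposed to.
#'
#' @param sid study id.
#' @param j reader index.
#' @param state a radiology state (see [rad_init_state()]).
#' @return Numeric vector of length 7.
#' @export
featurize_rad_pair <- function(sid, j, state) {
  if (sid < 1L || sid > state$n) stop_invalid("unknown study id ", sid)
  pool <- state$pools[[j]]
  frac <- if (length(pool)) mean(state$in_sub[pool, j]) else 0
  overdue <- if (length(pool)) sum(state$due[pool] < state$now) else 0L
  lateness <- (state$now - state$due[sid]) / 60
  v <- c(as.numeric(state$in_sub[sid, j]), frac, overdue, lateness,
         state$breadth[sid], -lateness, .exposure_count(state, sid))
  names(v) <- rad_schema()$feature_names
  v
}

#' Naive exposure policy: every pending study in every reader's pool
#'
#' @param state a radiology state.
#' @return List of pools (one integer vector of study ids per reader).
#' @export
naive_expose <- function(state) {
  pend <- which(state$status == 1L)
  lapply(seq_along(state$subspec), function(j) pend)
}

#' Interval heuristic exposure policy (H)
#'
#' Divides each study's arrival-to-deadline interval into three equal parts:
#' during the first third the study is exposed only to readers holding its
#' exact type in their subspecialty; during the second third to the wider
#' group of readers sharing its modality; from the final third (and past the
#' deadline) to all readers until it is read.
#'
#' @param state a radiology state.
#' @param now current time in minutes (default `state$now`).
#' @return List of pools per reader.
#' @export
h_expose <- function(state, now = state$now) {
  pend <- which(state$status == 1L)
  third <- state$deadline_min[pend] / 3
  phase1 <- now < state$arrival[pend] + third
  phase2 <- !phase1 & now < state$arrival[pend] + 2 * third
  lapply(seq_along(state$subspec), function(j) {
    mods <- unique(sub("\\|.*$", "", state$subspec[[j]]))
    keep <- !phase1 & !phase2
    keep <- keep | (phase1 & state$in_sub[pend, j])
    keep <- keep | (phase2 & state$M[pend] %in% mods)
    pend[keep]
  })
}

#' Learned exposure update at a study arrival
#'
#' For every reader in parallel: if the reader's pool is below the cap `k`,
#' the new study is inserted at its comparator rank; if the pool is full, the
#' new study is compared with the reader's lowest-ranking pending study and
#' replaces it (pool-locally) when the comparator weakly prefers the new one.
#' If no reader ends up holding the study, it is exposed to the single
#' best-scoring reader so no study is orphaned.
#'
#' @param model a trained [comparator()] on the [rad_schema()].
#' @param state a radiology state.
#' @param sid the arriving study's id.
#' @return The updated state.
#' @export
dnn_expose_on_arrival <- function(model, state, sid) {
  R <- length(state$pools)
  scores <- numeric(R)
  exposed <- FALSE
  for (j in seq_len(R)) {
    pool <- state$pools[[j]]
    newf <- featurize_rad_pair(sid, j, state)
    if (length(pool) < state$k) {
      poolf <- do.call(rbind, lapply(pool, featurize_rad_pair, j = j, state = state))
      ins <- insert_by_partial_order(model, poolf %||% matrix(numeric(0), 0, 7L), newf)
      state$pools[[j]] <- append(pool, sid, after = ins$position - 1L)
      exposed <- TRUE
      scores[j] <- 1
    } else {
      worst <- pool[length(pool)]
      sc <- compare(model, newf, featurize_rad_pair(worst, j, state))
      scores[j] <- sc
      if (sc >= 0.5) {
        pool <- pool[-length(pool)]
        poolf <- do.call(rbind, lapply(pool, featurize_rad_pair, j = j, state = state))
        ins <- insert_by_partial_order(model, poolf %||% matrix(numeric(0), 0, 7L), newf)
        state$pools[[j]] <- append(pool, sid, after = ins$position - 1L)
        exposed <- TRUE
      }
    }
  }
  if (!exposed) { # zero-exposure guard
    j <- which.max(scores)
    pool <- state$pools[[j]]
    if (length(pool) >= state$k) pool <- pool[-length(pool)]
    state$pools[[j]] <- c(pool, sid)
  }
  state
}

#' Learned exposure update at a reading completion
#'
#' All pending studies not exposed to the reader are ranked with the
#' comparator (a linear scan keeping the pairwise-preferred study, which
#' under a transitive comparator is the maximum) and the highest-ranking one
#' is added to the reader's pool at its comparator rank, respecting the cap.
#'
#' @param model a trained [comparator()].
#' @param state a radiology state.
#' @param j the reader who just completed a reading.
#' @return The updated state.
#' @export
dnn_expose_on_completion <- function(model, state, j) {
  if (length(state$pools[[j]]) >= state$k) return(state)
  pend <- which(state$status == 1L)
  cand <- setdiff(pend, state$pools[[j]])
  if (!length(cand)) return(state)
  best <- cand[1L]
  if (length(cand) > 1L) {
    bestf <- featurize_rad_pair(best, j, state)
    for (s in cand[-1L]) {
      sf <- featurize_rad_pair(s, j, state)
      if (compare(model, sf, bestf) >= 0.5) {
        best <- s
        bestf <- sf
      }
    }
  }
  pool <- state$pools[[j]]
  poolf <- do.call(rbind, lapply(pool, featurize_rad_pair, j = j, state = state))
  ins <- insert_by_partial_order(model, poolf %||% matrix(numeric(0), 0, 7L),
                                 featurize_rad_pair(best, j, state))
  state$pools[[j]] <- append(pool, best, after = ins$position - 1L)
  state
}
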