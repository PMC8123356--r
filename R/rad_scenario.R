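# Radiology study/reader scenario generation: study streams from a
# non-homogeneous arrival profile, reader subspecialties, and revealed-
# preference utilities estimated from a synthetic selection history.

#' Radiology scenario configuration
#'
#' Defaults mirror the reading-room study conditions: 10 readers, 60 studies,
#' pool cap `k = 10`, deadlines between 30 minutes and 1 week, nominal
#' reading time 3 minutes within the reader's subspecialty and
#' `rho = 3` times that outside it.
#'
#' @param modalities,body_parts categorical sets defining the study types
#'   (modality x body part).
#' @param n_readers number of readers.
#' @param n_studies number of studies in the stream.
#' @param k pool cap for the learned exposure policy.
#' @param window_min arrival window in minutes (default 20: a batch of
#'   studies landing faster than the room can absorb, so a backlog forms,
#'   the pool cap binds and deadline pressure is real).
#' @param rates_per_hour relative arrival-rate profile over the window
#'   (piecewise-constant per hour, recycled; only the shape matters since the
#'   study count is fixed). All-zero rates give an empty stream.
#' @param deadline_range_min deadline range (minutes after arrival).
#' @param deadline_mean_min mean of the exponential deadline draw above the
#'   30-minute floor (truncated at the range maximum). The default 120 skews
#'   deadlines towards the acute end -- most studies due within a few hours,
#'   a tail out to a week -- so queueing delays are commensurate with
#'   deadlines and exposure policy actually matters.
#' @param nominal_read_min nominal reading time `T(M, B)` (minutes).
#' @param rho skill-efficiency factor (> 1) for out-of-subspecialty reading.
#' @param subspec_size number of modality-body-part pairs per reader's
#'   subspecialty (default 2: subspecialists are narrow, so some study types
#'   have no subspecialist among the readers).
#' @param history_len synthetic selection-history length per reader used by
#'   [estimate_utilities()].
#' @param history_boost additive log-utility bonus for in-subspecialty types
#'   in the synthetic history generator.
#' @return A list of class `rad_config`.
#' @export
rad_config <- function(modalities = c("CT", "MRI", "US", "XR"),
                       body_parts = c("head", "chest", "abdomen", "spine", "limb"),
                       n_readers = 10L, n_studies = 60L, k = 10L,
                       window_min = 20,
                       rates_per_hour = 1,
                       deadline_range_min = c(30, 10080),
                       deadline_mean_min = 120,
                       nominal_read_min = 3, rho = 3,
                       subspec_size = 2L,
                       history_len = 200L,
                       history_boost = 1.5) {
  if (!length(modalities)) stop_invalid("modality set must be nonempty")
  if (!length(body_parts)) stop_invalid("body-part set must be nonempty")
  stopifnot(rho > 1, nominal_read_min > 0, n_readers >= 1,
            deadline_range_min[1] > 0,
            deadline_range_min[2] >= deadline_range_min[1])
  if (any(rates_per_hour < 0)) stop_invalid("arrival rates must be non-negative")
  structure(list(
    modalities = modalities, body_parts = body_parts,
    types = as.vector(outer(modalities, body_parts, paste, sep = "|")),
    n_readers = as.integer(n_readers), n_studies = as.integer(n_studies),
    k = as.integer(k), window_min = window_min,
    rates_per_hour = rates_per_hour,
    deadline_range_min = deadline_range_min,
    deadline_mean_min = deadline_mean_min,
    nominal_read_min = nominal_read_min, rho = rho,
    subspec_size = as.integer(subspec_size),
    history_len = as.integer(history_len), history_boost = history_boost
  ), class = "rad_config")
}

#' Small-scenario radiology configuration for policy training
#'
#' The tree search that produces training decisions is simulation-heavy, so
#' training scenarios are scaled down while keeping the same congestion
#' intensity (arrivals per minute) as the evaluation conditions.
#'
#' @param ... overrides passed to [rad_config()].
#' @return A `rad_config`.
#' @export
rad_training_config <- function(n_studies = 30L, window_min = 10, ...) {
  rad_config(n_studies = n_studies, window_min = window_min, ...)
}

#' Estimate reader utilities from a selection history
#'
#' Revealed-preference proxy: a reader's utility for a study type is the
#' normalized frequency with which they selected that type; unseen types get
#' utility 0. A reader with an empty history gets a uniform utility with a
#' warning.
#'
#' @param history list, one character vector of selected type keys
#'   (`"M|B"`) per reader.
#' @param types character vector of all type keys.
#' @return List of named numeric utility vectors (each summing to 1).
#' @export
#' @examples
#' estimate_utilities(list(c("CT|head", "CT|head", "MRI|chest")),
#'                    c("CT|head", "MRI|chest"))
estimate_utilities <- function(history, types) {
  lapply(seq_along(history), function(j) {
    h <- history[[j]]
    u <- stats::setNames(numeric(length(types)), types)
    if (!length(h)) {
      warning("reader ", j, " has an empty selection history; using uniform utility")
      u[] <- 1 / length(types)
      return(u)
    }
    tab <- table(factor(h, levels = types))
    u[] <- as.numeric(tab) / length(h)
    u
  })
}

#' Nominal-or-penalised reading time
#'
#' `T(M, B)` minutes if the study's type is within the reader's subspecialty,
#' else `rho * T(M, B)` (the skill-efficiency factor `rho > 1`).
#'
#' @param reader_subspec character vector of the reader's subspecialty type
#'   keys (`"M|B"`).
#' @param study_type the study's type key.
#' @param cfg a [rad_config()] (supplies `T(M, B)` and `rho`).
#' @return Reading time in minutes.
#' @export
reading_time <- function(reader_subspec, study_type, cfg = rad_config()) {
  if (!(study_type %in% cfg$types)) {
    stop_invalid("unknown study type '", study_type, "'")
  }
  if (study_type %in% reader_subspec) cfg$nominal_read_min
  else cfg$rho * cfg$nominal_read_min
}

#' Quantal-response choice probabilities over a reader's pool
#'
#' Softmax of the reader's utilities over the studies in the pool:
#' \eqn{p(s_i) = e^{u(s_i)} / \sum_k e^{u(s_k)}}.
#'
#' @param utilities numeric vector of the reader's utilities for the pool's
#'   studies (in pool order).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(1, 0)) # c(e, 1) / (e + 1)
choice_probabilities <- function(utilities) {
  if (!length(utilities)) stop_invalid("choice over an empty pool")
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' Generate a radiology reading-room scenario
#'
#' Draws a stream of `n_studies` studies (modality, body part, floor-plus-
#' exponential deadline, arrival time positioned by the configured non-homogeneous rate
#' profile over the window) and `n_readers` readers with sampled
#' subspecialties and revealed-preference utilities estimated from a
#' synthetic selection history (each reader's history is drawn from a softmax
#' over type preferences boosted on their subspecialty, then fed to
#' [estimate_utilities()]). Fully reproducible from `seed`.
#'
#' @param cfg a [rad_config()].
#' @param seed integer seed.
#' @return An object of class `rad_scenario`: `studies` data frame (id, M, B,
#'   type, arrival, deadline_min, due), `subspec` (list per reader),
#'   `utility` (list per reader), `cfg`, `seed`.
#' @export
generate_radiology_scenario <- function(cfg = rad_config(), seed = 1L) {
  stopifnot(inherits(cfg, "rad_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rates <- rep_len(cfg$rates_per_hour, max(1L, ceiling(cfg$window_min / 60)))
  bin_w <- cfg$window_min / length(rates)
  n <- if (sum(rates) == 0) 0L else cfg$n_studies
  # position arrivals by inverse transform of the normalized cumulative rate
  arr <- numeric(0)
  if (n > 0) {
    cum <- cumsum(rates) / sum(rates)
    u <- sort(runif(n))
    arr <- vapply(u, function(q) {
      h <- which(q <= cum)[1L]
      lo <- if (h == 1L) 0 else cum[h - 1L]
      frac <- (q - lo) / (cum[h] - lo)
      ((h - 1L) + frac) * bin_w
    }, numeric(1))
    arr <- pmin(arr, cfg$window_min - 1e-9)
  }
  mods <- sample(cfg$modalities, n, replace = TRUE)
  parts <- sample(cfg$body_parts, n, replace = TRUE)
  dl <- pmin(cfg$deadline_range_min[1] + rexp(n, 1 / cfg$deadline_mean_min),
             cfg$deadline_range_min[2])
  studies <- data.frame(
    id = if (n) seq_len(n) else integer(0),
    M = mods, B = parts, type = paste(mods, parts, sep = "|"),
    arrival = arr, deadline_min = dl, due = arr + dl,
    stringsAsFactors = FALSE
  )
  if (n == 0L) studies <- studies[0, , drop = FALSE]
  subspec <- lapply(seq_len(cfg$n_readers), function(j) {
    sample(cfg$types, min(cfg$subspec_size, length(cfg$types)))
  })
  history <- lapply(seq_len(cfg$n_readers), function(j) {
    w <- stats::setNames(rep(0, length(cfg$types)), cfg$types)
    w[subspec[[j]]] <- cfg$history_boost
    pr <- exp(w) / sum(exp(w))
    sample(cfg$types, cfg$history_len, replace = TRUE, prob = pr)
  })
  utility <- estimate_utilities(history, cfg$types)
  structure(list(studies = studies, subspec = subspec, utility = utility,
                 history = history, cfg = cfg, seed = as.integer(seed)),
            class = "rad_scenario")
}

#' @export
print.rad_scenario <- function(x, ...) {
  cat("<rad_scenario>", nrow(x$studies), "studies,", length(x$subspec),
      "readers (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write / read a radiology scenario as JSON
#' @param scenario a `rad_scenario`.
#' @param path file path.
#' @return `path` (write) or the scenario (read).
#' @export
write_rad_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "rad_scenario"))
  obj <- list(format = "lbassign-rad-scenario-v1",
              studies = scenario$studies,
              subspec = scenario$subspec,
              utility = lapply(scenario$utility, as.list),
              types = scenario$cfg$types,
              k = scenario$cfg$k,
              nominal_read_min = scenario$cfg$nominal_read_min,
              rho = scenario$cfg$rho,
              seed = scenario$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rad_scenario
#' @export
read_rad_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "lbassign-rad-scenario-v1")) {
    stop_invalid("not a radiology scenario file: ", path)
  }
  studies <- do.call(rbind, lapply(obj$studies, function(r) {
    data.frame(id = r$id, M = r$M, B = r$B, type = r$type,
               arrival = r$arrival, deadline_min = r$deadline_min,
               due = r$due, stringsAsFactors = FALSE)
  }))
  if (is.null(studies)) {
    studies <- data.frame(id = integer(0), M = character(0), B = character(0),
                          type = character(0), arrival = numeric(0),
                          deadline_min = numeric(0), due = numeric(0))
  }
  cfg <- rad_config(n_readers = length(obj$subspec),
                    n_studies = nrow(studies),
                    k = obj$k, nominal_read_min = obj$nominal_read_min,
                    rho = obj$rho)
  cfg$types <- as.character(unlist(obj$types))
  structure(list(studies = studies,
                 subspec = lapply(obj$subspec, function(s) as.character(unlist(s))),
                 utility = lapply(obj$utility, function(u) {
                   stats::setNames(as.numeric(unlist(u)), names(u))
                 }),
                 cfg = cfg, seed = as.integer(obj$seed)),
            class = "rad_scenario")
}
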