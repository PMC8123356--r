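# ED scenario generation: non-homogeneous Poisson arrivals (thinning),
# severities, injuries, treatment/lab time draws, slot discretisation.

#' Sample event times from a non-homogeneous Poisson process by thinning
#'
#' @param rate_fn vectorised function of time returning the instantaneous rate
#'   (events per time unit); must be non-negative on `[0, t_max]`.
#' @param t_max end of the window.
#' @param rate_max an upper bound on the rate over the window.
#' @return Sorted numeric vector of event times in `[0, t_max)`.
#' @export
nhpp_times <- function(rate_fn, t_max, rate_max) {
  stopifnot(t_max >= 0, rate_max >= 0)
  if (rate_max == 0 || t_max == 0) return(numeric(0))
  out <- numeric(0)
  t <- 0
  repeat {
    t <- t + rexp(1L, rate_max)
    if (t >= t_max) break
    lam <- rate_fn(t)
    if (lam < 0) stop_invalid("arrival rate function is negative at t = ", t)
    if (lam > rate_max + 1e-9) stop_invalid("rate_max is not an upper bound of the rate function")
    if (runif(1L) < lam / rate_max) out <- c(out, t)
  }
  out
}

.ed_rate_fn <- function(cfg) {
  rates <- rep_len(cfg$rates_per_hour, ceiling(cfg$shift_min / 60))
  function(t) {
    idx <- clip(floor(t / 60) + 1, 1, length(rates))
    rates[idx] / 60 * cfg$flow # per minute
  }
}

# round a duration (minutes) up to whole slots, at least 1 slot
.to_slots <- function(min, slot_min) pmax(1L, as.integer(ceiling(min / slot_min)))

#' Generate an ED night-shift scenario
#'
#' Draws patient arrivals from the configured non-homogeneous Poisson process
#' (thinning), assigns severities, injury types, triage wait bounds, nominal
#' treatment times, lab times and second-examination indicators, and
#' discretises all times to the slot grid. Fully reproducible from `seed`.
#'
#' @param cfg an [ed_config()].
#' @param seed integer seed.
#' @return An object of class `ed_scenario`: list with `patients` (data
#'   frame), `physicians`, `horizon` (number of slots `T`), `slot_min`, `cfg`
#'   and `seed`. Patient columns include both minute-level quantities
#'   (`arrival_min`, `tt1_min`, ...) and their slot-grid versions (`arrival`,
#'   `tt1`, ... in slots).
#' @export
#' @examples
#' sc <- generate_ed_scenario(ed_training_config(), seed = 1)
#' nrow(sc$patients)
generate_ed_scenario <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ed_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rate_fn <- .ed_rate_fn(cfg)
  rate_max <- max(cfg$rates_per_hour) / 60 * cfg$flow
  arr <- nhpp_times(rate_fn, cfg$shift_min, rate_max)
  if (length(arr) > cfg$max_patients) arr <- arr[seq_len(cfg$max_patients)]
  n <- length(arr)
  sev <- sample.int(5L, n, replace = TRUE, prob = cfg$severity_probs)
  inj <- sample(cfg$injuries, n, replace = TRUE, prob = cfg$injury_probs)
  needs2 <- runif(n) < cfg$second_exam_prob
  r5 <- function(rg) 5 * round(runif(n, rg[1], rg[2]) / 5) # 5-min granular draws
  tt1 <- pmax(cfg$slot_min, r5(cfg$tt1_range))
  tt2 <- ifelse(needs2, pmax(cfg$slot_min, r5(cfg$tt2_range)), 0)
  lt <- ifelse(needs2, pmax(0, r5(cfg$lt_range)), 0)
  patients <- data.frame(
    id = if (n) paste0("p", seq_len(n)) else character(0),
    arrival_min = arr,
    severity = sev,
    injury = inj,
    needs_second = needs2,
    tt1_min = tt1, tt2_min = tt2, lt_min = lt,
    tbar1_min = cfg$wait_bounds_min[sev],
    tbar2_min = cfg$wait_bounds_min[sev],
    stringsAsFactors = FALSE
  )
  slot <- cfg$slot_min
  patients$arrival <- as.integer(floor(patients$arrival_min / slot))
  patients$tt1 <- if (n) .to_slots(patients$tt1_min, slot) else integer(0)
  patients$tt2 <- ifelse(patients$needs_second, .to_slots(patients$tt2_min, slot), 0L)
  patients$lt <- as.integer(ceiling(patients$lt_min / slot))
  patients$tbar1 <- as.integer(ceiling(patients$tbar1_min / slot))
  patients$tbar2 <- as.integer(ceiling(patients$tbar2_min / slot))
  structure(list(
    patients = patients,
    physicians = cfg$physicians,
    horizon = as.integer(ceiling(cfg$shift_min / slot)),
    slot_min = slot,
    cfg = cfg, seed = as.integer(seed)
  ), class = "ed_scenario")
}

#' @export
print.ed_scenario <- function(x, ...) {
  cat("<ed_scenario>", nrow(x$patients), "patients,",
      nrow(x$physicians), "physicians, horizon", x$horizon, "slots of",
      x$slot_min, "min (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write / read an ED scenario as JSON
#' @param scenario an `ed_scenario`.
#' @param path file path.
#' @return `path` (write) or the scenario (read).
#' @export
write_ed_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ed_scenario"))
  obj <- list(format = "lbassign-ed-scenario-v1",
              patients = scenario$patients,
              physicians = scenario$physicians,
              horizon = scenario$horizon, slot_min = scenario$slot_min,
              seed = scenario$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_ed_scenario
#' @export
read_ed_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lbassign-ed-scenario-v1")) {
    stop_invalid("not an ED scenario file: ", path)
  }
  pats <- as.data.frame(obj$patients)
  if (!nrow(pats)) {
    pats <- generate_ed_scenario(ed_config(rates_per_hour = 0), seed = 1)$patients
  }
  structure(list(patients = pats,
                 physicians = as.data.frame(obj$physicians),
                 horizon = as.integer(obj$horizon),
                 slot_min = obj$slot_min,
                 cfg = NULL, seed = as.integer(obj$seed)),
            class = "ed_scenario")
}
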