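# Event-driven simulation of an ED shift under an online assignment policy,
# with the five-component objective accounting mirrored on the offline solver
# (so a simulated replay of an offline schedule scores identically).

#' Simulate an ED shift under an online policy
#'
#' Runs the common ED work-flow on the slot grid: arrival, wait for the first
#' examination, treatment (occupying `CE * TT` slots for the treating
#' physician), optional lab tests, wait for the second examination, second
#' treatment, discharge. The policy is consulted at every event (arrival, lab
#' return, treatment completion) and may assign waiting patients to idle
#' physicians or preempt busy ones; preempted patients return to the queue
#' with their remaining treatment time (work-preserving) and their restart
#' incurs the preemption penalty. The simulation continues past the shift end
#' until all patients are discharged or the overtime allowance runs out;
#' patients still present then are charged their stay up to the horizon plus a
#' terminal penalty proportional to their remaining nominal treatment minutes.
#'
#' Identical `seed`, policy and scenario give an identical trace.
#'
#' @param policy `"fcfswu"`, `"lba"` (requires `model`), or a function
#'   `state -> assignments` (see [fcfswu_decide()] for the contract).
#' @param scenario an `ed_scenario`.
#' @param weights an [ed_weights()].
#' @param seed integer seed (used for the policy's random tie-breaking).
#' @param model a trained [comparator()] (for `policy = "lba"`).
#' @param schema an [ed_schema()]; default derived from the scenario.
#' @param max_overtime_min overtime allowance past the shift end (default 240).
#' @return An object of class `shift_metrics`: five objective components in
#'   natural units (`risk`, `wait` = excess-wait penalty, `los` minutes,
#'   `crowd` patient-minutes, `preempt` penalty), the preemption count, the
#'   crowding trace `kappa`, per-patient wait/LOS records and the weighted
#'   objective score.
#' @export
simulate_shift <- function(policy, scenario, weights = ed_weights(), seed = 1L,
                           model = NULL, schema = NULL,
                           max_overtime_min = 240) {
  stopifnot(inherits(scenario, "ed_scenario"), inherits(weights, "ed_weights"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- scenario$patients
  phd <- scenario$physicians
  n <- nrow(p)
  m <- nrow(phd)
  slot <- scenario$slot_min
  if (is.null(schema)) {
    injuries <- if (!is.null(scenario$cfg)) scenario$cfg$injuries else
      sort(unique(c(p$injury, phd$specialty[!is.na(phd$specialty)])))
    schema <- ed_schema(injuries)
  }
  policy_fn <- switch(
    if (is.function(policy)) "custom" else policy,
    fcfswu = function(state) fcfswu_decide(state),
    lba = {
      if (is.null(model)) stop_invalid("policy 'lba' requires a trained comparator model")
      function(state) lba_decide(model, state, schema)
    },
    custom = policy,
    stop_invalid("unknown policy '", policy, "'")
  )
  ce <- as.integer(phd$ce)
  scale <- Reduce(.lcm2, ce)
  red <- as.integer(scale / ce)
  full1 <- as.integer(p$tt1 * scale)
  full2 <- as.integer(p$tt2 * scale)
  Tmax <- scenario$horizon + as.integer(ceiling(max_overtime_min / slot))

  phase <- rep(0L, n) # 0 wait/treat exam1, 1 lab, 2 wait/treat exam2, 3 done
  rem <- full1
  aux <- rep(0L, n)
  mask1 <- mask2 <- rep(0L, n)
  st <- et <- matrix(NA_integer_, max(n, 1L), 2L)
  wt_min <- matrix(NA_real_, max(n, 1L), 2L)
  los_min_i <- rep(NA_real_, max(n, 1L))
  busy_patient <- rep(0L, m)
  busy_exam <- rep(0L, m)
  last_busy_end <- rep(0L, m)
  comp <- c(risk = 0, wait = 0, los = 0, crowd = 0, preempt = 0)
  pre_count <- 0L
  kappa <- integer(Tmax)
  pending_event <- FALSE

  build_state <- function(t) {
    rows <- list()
    for (i in seq_len(n)) {
      if (phase[i] == 0L && t >= p$arrival[i] && !(i %in% busy_patient)) {
        e <- 1L; arr <- p$arrival[i]; tbar <- p$tbar1_min[i]
      } else if (phase[i] == 2L && !(i %in% busy_patient)) {
        e <- 2L; arr <- aux[i]; tbar <- p$tbar2_min[i]
      } else next
      rows[[length(rows) + 1L]] <- data.frame(
        idx = i, exam = e, arr = arr,
        severity = p$severity[i], injury = p$injury[i],
        wait_min = (t - arr) * slot,
        remaining_tt_min = rem[i] / scale * slot,
        tbar_min = tbar, stringsAsFactors = FALSE)
    }
    waiting <- if (length(rows)) do.call(rbind, rows) else
      data.frame(idx = integer(0), exam = integer(0), arr = integer(0),
                 severity = integer(0), injury = character(0),
                 wait_min = numeric(0), remaining_tt_min = numeric(0),
                 tbar_min = numeric(0))
    physicians <- data.frame(
      id = phd$id, seniority = phd$seniority, specialty = phd$specialty,
      ce = phd$ce,
      busy_patient = busy_patient, busy_exam = busy_exam,
      busy_severity = ifelse(busy_patient > 0L, p$severity[pmax(busy_patient, 1L)], 0L),
      idle_min = ifelse(busy_patient > 0L, 0, (t - last_busy_end) * slot),
      stringsAsFactors = FALSE)
    list(t = t, slot_min = slot, waiting = waiting, physicians = physicians)
  }

  apply_assignments <- function(dec, t) {
    for (r in seq_len(nrow(dec))) {
      i <- dec$patient[r]
      j <- dec$physician[r]
      e <- dec$exam[r]
      if (j < 1L || j > m) next
      eligible <- (e == 1L && phase[i] == 0L && t >= p$arrival[i]) ||
        (e == 2L && phase[i] == 2L)
      if (!eligible || i %in% busy_patient) next
      if (busy_patient[j] > 0L) { # preemption: current patient back to queue
        last_busy_end[j] <<- t
        busy_patient[j] <<- 0L
        busy_exam[j] <<- 0L
      }
      full <- if (e == 1L) full1[i] else full2[i]
      if (rem[i] < full) { # restart of an interrupted examination
        comp[["preempt"]] <<- comp[["preempt"]] + weights$pre(p$severity[i], e)
        pre_count <<- pre_count + 1L
      } else {
        st[i, e] <<- t
        wt_min[i, e] <<- (t - (if (e == 1L) p$arrival[i] else aux[i])) * slot
      }
      bit <- bitwShiftL(1L, j - 1L)
      msk <- if (e == 1L) mask1[i] else mask2[i]
      if (bitwAnd(msk, bit) == 0L) {
        comp[["risk"]] <<- comp[["risk"]] +
          weights$risk(p$severity[i], p$injury[i], phd$seniority[j],
                       phd$specialty[j], e)
        if (e == 1L) mask1[i] <<- bitwOr(mask1[i], bit) else
          mask2[i] <<- bitwOr(mask2[i], bit)
      }
      busy_patient[j] <<- i
      busy_exam[j] <<- e
    }
  }

  for (t in 0:(Tmax - 1L)) {
    if (n == 0L || all(phase == 3L)) break
    event <- pending_event
    pending_event <- FALSE
    lab_done <- which(phase == 1L & aux <= t)
    if (length(lab_done)) {
      phase[lab_done] <- 2L
      event <- TRUE
    }
    if (any(p$arrival == t)) event <- TRUE
    if (event) {
      dec <- policy_fn(build_state(t))
      if (nrow(dec)) apply_assignments(dec, t)
    }
    present <- which(phase < 3L & t >= p$arrival)
    kappa[t + 1L] <- length(present)
    comp[["crowd"]] <- comp[["crowd"]] + length(present) * slot
    for (i in present) {
      if (i %in% busy_patient) next
      if (phase[i] == 0L && rem[i] == full1[i] && t >= p$arrival[i] + p$tbar1[i]) {
        comp[["wait"]] <- comp[["wait"]] + weights$exc(p$severity[i], 1L, slot)
      } else if (phase[i] == 2L && rem[i] == full2[i] && t >= aux[i] + p$tbar2[i]) {
        comp[["wait"]] <- comp[["wait"]] + weights$exc(p$severity[i], 2L, slot)
      }
    }
    for (j in seq_len(m)) {
      i <- busy_patient[j]
      if (i == 0L) next
      rem[i] <- rem[i] - red[j]
      if (rem[i] <= 0L) {
        e <- busy_exam[j]
        et[i, e] <- t + 1L
        if (e == 1L && p$needs_second[i]) {
          phase[i] <- 1L
          aux[i] <- t + 1L + p$lt[i]
          rem[i] <- full2[i]
        } else {
          phase[i] <- 3L
          los_min_i[i] <- (t + 1L - p$arrival[i]) * slot
          comp[["los"]] <- comp[["los"]] + los_min_i[i]
        }
        busy_patient[j] <- 0L
        busy_exam[j] <- 0L
        last_busy_end[j] <- t + 1L
        pending_event <- TRUE
      }
    }
  }
  terminal <- 0
  for (i in seq_len(n)) {
    if (phase[i] == 3L) next
    los_min_i[i] <- (Tmax - p$arrival[i]) * slot
    comp[["los"]] <- comp[["los"]] + los_min_i[i]
    rem_nominal_min <- rem[i] / scale * slot +
      if (phase[i] %in% c(0L, 1L) && p$needs_second[i] && phase[i] == 0L)
        (p$lt[i] + p$tt2[i]) * slot else if (phase[i] == 1L)
          max(aux[i] - Tmax, 0L) * slot else 0
    terminal <- terminal + weights$terminal_penalty_per_min * rem_nominal_min
  }
  structure(list(
    components = comp, terminal = terminal, pre_count = pre_count,
    kappa = kappa,
    per_patient = if (n) data.frame(
      id = p$id, severity = p$severity,
      wt1_min = wt_min[seq_len(n), 1L], wt2_min = wt_min[seq_len(n), 2L],
      los_min = los_min_i[seq_len(n)],
      completed = phase == 3L) else
        data.frame(id = character(0), severity = integer(0),
                   wt1_min = numeric(0), wt2_min = numeric(0),
                   los_min = numeric(0), completed = logical(0)),
    policy = if (is.function(policy)) "custom" else policy,
    seed = as.integer(seed),
    objective = unname(sum(weights$alpha * comp)) + terminal
  ), class = "shift_metrics")
}

#' @export
print.shift_metrics <- function(x, ...) {
  cat("<shift_metrics> policy:", x$policy, " objective:",
      signif(x$objective, 6), "\n  components:",
      paste(names(x$components), signif(x$components, 4), sep = "=",
            collapse = " "),
      " preemptions:", x$pre_count, "\n")
  invisible(x)
}

#' The weighted five-component ED objective
#'
#' Applies the configured weights to the objective components: risk of
#' adverse consequences, excess-wait penalties, length of stay, crowding
#' integral and preemption penalties (plus any terminal penalty for patients
#' unfinished at the horizon). Accepts either a [simulate_shift()] result or
#' a [solve_offline()] schedule.
#'
#' @param metrics a `shift_metrics` or `schedule_solution`.
#' @param weights an [ed_weights()].
#' @return The scalar objective score.
#' @export
ed_objective <- function(metrics, weights = ed_weights()) {
  comp <- metrics$components
  stopifnot(!is.null(comp))
  unname(sum(weights$alpha * comp[names(weights$alpha)])) +
    (metrics$terminal %||% 0)
}
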