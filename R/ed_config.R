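# Emergency-department configuration: scenario generator parameters and the
# five-component objective. The institutional constants behind a real ED's
# objective (risk tables, excess-wait penalties, preemption penalties) are
# site-specific; the defaults below are documented package defaults, not
# estimates of any particular hospital.

ED_SENIORITY <- c("assistant", "intern", "resident", "attending")

#' Default ED physician roster
#'
#' A night-shift roster of 2-4 physicians of mixed seniority and specialty.
#' `ce` is the time-efficiency factor: treatment by this physician occupies
#' `ce * TT` time slots (`ce >= 1`; 1 = fastest).
#'
#' @param n number of physicians (2-4).
#' @return A data frame with columns `id`, `seniority`, `specialty`, `ce`.
#' @export
ed_physicians <- function(n = 3L) {
  stopifnot(n >= 1L, n <= 4L)
  roster <- data.frame(
    id = paste0("c", 1:4),
    seniority = c("attending", "intern", "resident", "assistant"),
    specialty = c("internal", NA, "orthopedic", NA),
    ce = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  roster[seq_len(n), , drop = FALSE]
}

#' ED scenario-generator configuration
#'
#' Describes the night shift emulated by [generate_ed_scenario()]: a
#' non-homogeneous Poisson arrival process over the shift, severity and injury
#' mixes, treatment/lab-time distributions and the physician roster. Times are
#' minutes; the schedule is discretised to `slot_min`-minute slots.
#'
#' @param injuries character vector of injury/condition types.
#' @param injury_probs arrival probabilities per injury type.
#' @param severity_probs probabilities of triage severities 1..5 (1 most acute).
#' @param shift_min shift length in minutes (default 480, an 8-hour night
#'   shift).
#' @param slot_min slot length in minutes (default 5; all durations are
#'   rounded up to whole slots).
#' @param rates_per_hour piecewise-constant arrival rate (patients/hour), one
#'   value per hour of the shift; recycled as needed. The default profile
#'   tapers from the evening peak towards the small hours and picks up again
#'   before the morning.
#' @param flow flow multiplier applied to the rate function: 1 = normal flow,
#'   2 = heavy flow (twice the expected number of patients).
#' @param second_exam_prob probability that a patient needs lab work and a
#'   second examination (default 0.4).
#' @param tt1_range,tt2_range,lt_range minute ranges (uniform, rounded to the
#'   slot grid) for the first examination, second examination and lab tests.
#' @param wait_bounds_min triage wait-time upper bound (minutes) per severity
#'   1..5; waits beyond the bound are penalised.
#' @param physicians roster data frame, see [ed_physicians()].
#' @param max_patients cap on the number of arrivals kept (exact offline
#'   solving is exponential in the patient count; `Inf` disables the cap).
#' @return A list of class `ed_config`.
#' @export
ed_config <- function(injuries = c("internal", "orthopedic", "trauma"),
                      injury_probs = c(0.5, 0.3, 0.2),
                      severity_probs = c(0.03, 0.12, 0.35, 0.35, 0.15),
                      shift_min = 480,
                      slot_min = 5,
                      rates_per_hour = c(6, 5, 4, 3, 2, 2, 3, 4),
                      flow = 1,
                      second_exam_prob = 0.4,
                      tt1_range = c(10, 30),
                      tt2_range = c(5, 15),
                      lt_range = c(20, 40),
                      wait_bounds_min = c(0, 10, 30, 60, 120),
                      physicians = ed_physicians(3L),
                      max_patients = Inf) {
  stopifnot(length(injuries) >= 1, length(injury_probs) == length(injuries),
            abs(sum(injury_probs) - 1) < 1e-8,
            length(severity_probs) == 5, abs(sum(severity_probs) - 1) < 1e-8,
            shift_min > 0, slot_min > 0, flow > 0,
            second_exam_prob >= 0, second_exam_prob <= 1,
            length(wait_bounds_min) == 5)
  if (any(rates_per_hour < 0)) stop_invalid("arrival rates must be non-negative")
  if (!all(physicians$ce >= 1)) stop_invalid("physician efficiency factors must be >= 1")
  bad <- !is.na(physicians$specialty) & !(physicians$specialty %in% injuries)
  if (any(bad)) stop_invalid("physician specialty outside the injury types")
  structure(list(
    injuries = injuries, injury_probs = injury_probs,
    severity_probs = severity_probs,
    shift_min = shift_min, slot_min = slot_min,
    rates_per_hour = rates_per_hour, flow = flow,
    second_exam_prob = second_exam_prob,
    tt1_range = tt1_range, tt2_range = tt2_range, lt_range = lt_range,
    wait_bounds_min = wait_bounds_min,
    physicians = physicians, max_patients = max_patients
  ), class = "ed_config")
}

#' Small-scenario ED configuration for offline training
#'
#' Offline optima are computed exactly, so the training scenarios are kept
#' small-scale: a two-hour window opening with an arrival burst, an
#' attending-plus-intern roster, and an intensity that exceeds what the
#' attending alone can absorb. The burst matters for identification: a
#' clairvoyant offline optimum seats a patient it intends for the junior
#' physician immediately, so in quiet scenarios "has already waited" would
#' spuriously mark patients the optimum is holding for senior staff, and a
#' comparator imitating those decisions would refuse to seat exactly the
#' patients that have waited longest. A backlogged opening forces the
#' optimum to hand long-waiting patients to the junior physician as well,
#' so the training pairs cover both sides of that boundary. Treatment and
#' lab times are drawn slightly shorter than the full-shift ranges to keep
#' exact solving fast.
#'
#' @param ... overrides passed to [ed_config()].
#' @return An `ed_config`.
#' @export
ed_training_config <- function(shift_min = 120,
                               rates_per_hour = c(8, 0.5),
                               severity_probs = c(0.1, 0.2, 0.3, 0.25, 0.15),
                               tt1_range = c(10, 25),
                               tt2_range = c(5, 10),
                               lt_range = c(15, 30),
                               physicians = ed_physicians(2L),
                               max_patients = 5L, ...) {
  ed_config(shift_min = shift_min, rates_per_hour = rates_per_hour,
            severity_probs = severity_probs,
            tt1_range = tt1_range, tt2_range = tt2_range,
            lt_range = lt_range, physicians = physicians,
            max_patients = max_patients, ...)
}

#' ED objective weights and penalty tables
#'
#' The five-component objective: `alpha` weights risk of adverse consequences,
#' excess-wait penalties, length of stay, over-crowding and preemption
#' penalties. `risk(severity, injury, seniority, specialty, exam)` is the
#' adverse-consequence risk of one examination; `exc(severity, exam, dt)` the
#' penalty for exceeding the triage wait bound by `dt` minutes (zero at the
#' bound, non-decreasing); `pre(severity, exam)` the penalty per treatment
#' interruption. Defaults: risk = base-by-severity times a seniority multiplier
#' times a specialty-match factor; exc linear in `dt` with slope decreasing in
#' the severity number (acute patients are costlier to delay).
#'
#' @param alpha named numeric vector of length 5:
#'   `risk`, `wait`, `los`, `crowd`, `preempt`.
#' @param risk_base base risk per severity 1..5.
#' @param risk_seniority_mult multiplier per seniority
#'   (assistant, intern, resident, attending).
#' @param risk_match_mult multipliers: specialty matches the injury /
#'   no specialty / specialist in a different injury.
#' @param exc_slope penalty per excess minute, per severity 1..5.
#' @param pre_base preemption penalty per severity 1..5.
#' @param second_exam_risk_mult risk multiplier for the second examination.
#' @return A list of class `ed_weights` with elements `alpha` and functions
#'   `risk(severity, injury, seniority, specialty, exam)`,
#'   `exc(severity, exam, dt)`, `pre(severity, exam)`.
#' @export
ed_weights <- function(alpha = c(risk = 1, wait = 1, los = 0.05,
                                 crowd = 0.02, preempt = 1),
                       risk_base = c(8, 5, 3, 2, 1),
                       risk_seniority_mult = c(assistant = 2, intern = 1.6,
                                               resident = 1.3, attending = 1),
                       risk_match_mult = c(match = 0.8, none = 1, mismatch = 1.3),
                       exc_slope = c(2, 1, 0.4, 0.2, 0.1),
                       pre_base = c(40, 25, 12, 8, 5),
                       second_exam_risk_mult = 0.7) {
  stopifnot(length(alpha) == 5, all(alpha >= 0),
            length(risk_base) == 5, length(exc_slope) == 5,
            length(pre_base) == 5, all(exc_slope >= 0))
  names(alpha) <- c("risk", "wait", "los", "crowd", "preempt")
  risk <- function(severity, injury, seniority, specialty, exam) {
    mm <- if (is.na(specialty)) risk_match_mult[["none"]]
          else if (identical(specialty, injury)) risk_match_mult[["match"]]
          else risk_match_mult[["mismatch"]]
    em <- if (exam == 2L) second_exam_risk_mult else 1
    risk_base[severity] * risk_seniority_mult[[seniority]] * mm * em
  }
  exc <- function(severity, exam, dt) exc_slope[severity] * pmax(dt, 0)
  pre <- function(severity, exam) pre_base[severity]
  structure(list(alpha = alpha, risk = risk, exc = exc, pre = pre,
                 exc_slope = exc_slope, pre_base = pre_base,
                 terminal_penalty_per_min = unname(alpha[["los"]])),
            class = "ed_weights")
}
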