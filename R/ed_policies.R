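# Online assignment policies for the ED: the FCFSwU baseline heuristic and
# the learned comparator policy.
#
# Both act on an online decision state (built by the shift simulator, or
# constructed directly in tests):
#   state$t            current slot
#   state$slot_min     slot length (minutes)
#   state$waiting      data frame: idx, exam, arr (slot of this stage),
#                      severity, injury, wait_min, remaining_tt_min, tbar_min
#   state$physicians   data frame: id, seniority, specialty, ce,
#                      busy_patient (0 = idle), busy_exam,
#                      busy_severity (0 = idle), idle_min
# and return a data frame of assignments (patient, exam, physician) to apply
# now; assigning to a busy physician preempts their current patient.

#' First-Come-First-Served-with-Urgencies baseline
#'
#' The conventional ED heuristic. Patients of severity 3-5 form a single
#' non-urgent class served first-come-first-served by an idle physician who
#' either specializes in the relevant injury type or has no specialty; a
#' non-urgent patient is never assigned to a specialist in a different injury
#' type. Patients of severity 1-2 are urgent: the most senior specialized
#' physician not already treating another urgent patient is called, or
#' interrupted mid-treatment, to take them (a senior generalist if no matching
#' specialist is available, and only as a last resort a mismatched
#' specialist).
#'
#' @param state an ED decision state (see above).
#' @return Data frame of assignments (possibly zero rows) with columns
#'   `patient`, `exam`, `physician` (row index into `state$physicians`).
#' @export
fcfswu_decide <- function(state) {
  w <- state$waiting
  ph <- state$physicians
  out <- list()
  taken <- rep(FALSE, nrow(ph))
  if (nrow(w)) {
    urg <- w[w$severity <= 2, , drop = FALSE]
    urg <- urg[order(urg$severity, urg$arr), , drop = FALSE]
    for (r in seq_len(nrow(urg))) {
      p <- urg[r, ]
      cand <- which(!taken & !(ph$busy_severity %in% c(1, 2)))
      if (!length(cand)) next
      grp <- ifelse(!is.na(ph$specialty[cand]) & ph$specialty[cand] == p$injury, 0L,
                    ifelse(is.na(ph$specialty[cand]), 1L, 2L))
      sen <- match(ph$seniority[cand], ED_SENIORITY)
      j <- cand[order(grp, -sen)][1L]
      out[[length(out) + 1L]] <- data.frame(patient = p$idx, exam = p$exam,
                                            physician = j)
      taken[j] <- TRUE
    }
    nonu <- w[w$severity >= 3, , drop = FALSE]
    nonu <- nonu[order(nonu$arr), , drop = FALSE]
    for (r in seq_len(nrow(nonu))) {
      p <- nonu[r, ]
      cand <- which(!taken & ph$busy_patient == 0 &
                      (is.na(ph$specialty) | ph$specialty == p$injury))
      if (!length(cand)) next
      is_match <- !is.na(ph$specialty[cand]) & ph$specialty[cand] == p$injury
      sen <- match(ph$seniority[cand], ED_SENIORITY)
      j <- cand[order(!is_match, -sen)][1L]
      out[[length(out) + 1L]] <- data.frame(patient = p$idx, exam = p$exam,
                                            physician = j)
      taken[j] <- TRUE
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient = integer(0), exam = integer(0), physician = integer(0))
}

#' Enumerate the comparator's candidate assignments at a decision state
#'
#' One candidate per (waiting patient, physician) pair -- assigning to a busy
#' physician means preempting their current patient -- plus one wait-room
#' option per waiting patient (`physician = 0`).
#'
#' @param state an ED decision state.
#' @param schema an [ed_schema()].
#' @param exclude logical vector marking physicians unavailable this round
#'   (already given an assignment).
#' @return List with `features` (matrix, one candidate per row) and `meta`
#'   (data frame `patient`, `exam`, `physician`).
#' @export
ed_candidate_set <- function(state, schema, exclude = NULL) {
  w <- state$waiting
  ph <- state$physicians
  exclude <- exclude %||% rep(FALSE, nrow(ph))
  feats <- list()
  meta <- list()
  for (r in seq_len(nrow(w))) {
    p <- w[r, ]
    pat <- list(severity = p$severity, injury = p$injury,
                remaining_tt_min = p$remaining_tt_min,
                wait_min = p$wait_min, tbar_min = p$tbar_min)
    for (j in seq_len(nrow(ph))) {
      if (exclude[j]) next
      if (ph$busy_patient[j] == p$idx) next # already treating this patient
      phys <- list(seniority = ph$seniority[j], specialty = ph$specialty[j],
                   status_severity = ph$busy_severity[j],
                   idle_min = ph$idle_min[j])
      feats[[length(feats) + 1L]] <- featurize_ed_pair(pat, phys, schema)
      meta[[length(meta) + 1L]] <- data.frame(patient = p$idx, exam = p$exam,
                                              physician = j)
    }
    feats[[length(feats) + 1L]] <- featurize_ed_pair(pat, NULL, schema)
    meta[[length(meta) + 1L]] <- data.frame(patient = p$idx, exam = p$exam,
                                            physician = 0L)
  }
  list(
    features = if (length(feats)) do.call(rbind, feats) else
      matrix(numeric(0), 0, schema$length),
    meta = if (length(meta)) do.call(rbind, meta) else
      data.frame(patient = integer(0), exam = integer(0), physician = integer(0))
  )
}

#' Learned comparator policy for the ED
#'
#' At a decision state, all candidate assignments (every waiting patient
#' crossed with every physician, preemptive assignments included, plus the
#' wait-room options) are compared all-pairs with the trained comparator and
#' the majority-vote winner is applied. A wait-room winner applies to its
#' subject patient only (that patient keeps waiting); the vote then repeats
#' over the remaining candidates until every waiting patient has been seated
#' or sent to the wait room, or no physician is left to assign.
#'
#' @param model a trained [comparator()] on the ED schema.
#' @param state an ED decision state.
#' @param schema an [ed_schema()].
#' @return Data frame of assignments as in [fcfswu_decide()].
#' @export
lba_decide <- function(model, state, schema) {
  stopifnot(inherits(model, "comparator"))
  ph <- state$physicians
  out <- list()
  taken <- rep(FALSE, nrow(ph))
  w <- state$waiting
  guard <- nrow(w) + nrow(ph) + 1L
  while (nrow(w) > 0 && guard > 0) {
    guard <- guard - 1L
    cs <- ed_candidate_set(list(t = state$t, slot_min = state$slot_min,
                                waiting = w, physicians = ph), schema,
                           exclude = taken)
    if (!nrow(cs$features)) break
    kk <- majority_vote_select(model, cs$features)
    ch <- cs$meta[kk, ]
    if (ch$physician > 0L) {
      out[[length(out) + 1L]] <- ch
      taken[ch$physician] <- TRUE
    } # else: the winning option sends its subject patient to the wait room
    w <- w[!(w$idx == ch$patient & w$exam == ch$exam), , drop = FALSE]
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient = integer(0), exam = integer(0), physician = integer(0))
}
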