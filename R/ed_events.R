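# Translating offline-optimal ED schedules into decision events for
# comparator training.

#' Extract decision events from an offline-optimal schedule
#'
#' Walks the solved schedule and emits one decision event per assignment
#' instant: every patient arrival (first exam), lab return (second-exam
#' arrival) and treatment completion. The event's chosen option is what the
#' optimal solution did with the freed/new capacity at that instant -- a
#' fresh patient-physician treatment start, or the wait-room option when the
#' optimum left the queue untouched -- and the alternatives are all other
#' (waiting patient, physician) pairs available then (busy physicians
#' included, i.e. preemptive assignments) plus the wait-room options, each
#' featurized via [featurize_ed_pair()] from the offline state at that
#' instant.
#'
#' @param solution a [solve_offline()] (or [brute_force_schedule()]) result.
#' @param schema an [ed_schema()]; default derived from the scenario.
#' @return List of [decision_event()] objects, in time order. Events with no
#'   waiting patient carry zero options and are skipped (with a warning) by
#'   [build_training_pairs()].
#' @export
extract_decision_events <- function(solution, schema = NULL) {
  stopifnot(inherits(solution, "schedule_solution"))
  model <- solution$model
  scn <- model$scenario
  p <- scn$patients
  phd <- scn$physicians
  n <- model$n
  m <- model$m
  Tn <- model$T
  slot <- model$slot_min
  if (n == 0L) return(list())
  if (is.null(schema)) {
    injuries <- if (!is.null(scn$cfg)) scn$cfg$injuries else
      sort(unique(c(p$injury, phd$specialty[!is.na(phd$specialty)])))
    schema <- ed_schema(injuries)
  }
  y <- solution$y
  # per-slot treatment map: treat[t, j] = patient, texam[t, j] = exam
  treat <- matrix(0L, Tn, m)
  texam <- matrix(0L, Tn, m)
  for (t in seq_len(Tn)) {
    for (j in seq_len(m)) {
      for (e in 1:2) {
        ii <- which(y[, j, e, t])
        if (length(ii)) {
          treat[t, j] <- ii[1L]
          texam[t, j] <- e
        }
      }
    }
  }
  # cumulative delivered nominal work per patient-exam before each slot
  delivered_before <- function(i, e, t) {
    if (t == 0L) return(0)
    d <- 0
    for (j in seq_len(m)) d <- d + sum(y[i, j, e, seq_len(t)]) / model$ce[j]
    d
  }
  arr2 <- solution$arrival2
  events <- list()
  instant_slots <- sort(unique(c(
    p$arrival,
    arr2[!is.na(arr2)],
    as.vector(solution$et[!is.na(solution$et)])
  )))
  instant_slots <- instant_slots[instant_slots < Tn]
  last_busy_end <- function(j, t) {
    act <- which(treat[seq_len(max(t, 1L)), j] > 0L)
    act <- act[act <= t] # 1-based slots <= slot t-1 (0-based)
    if (length(act)) max(act) else 0L
  }
  for (t in instant_slots) {
    # pre-decision state at slot t (0-based): physicians continuing from t-1,
    # eligible waiting patients, fresh treatment starts made by the optimum
    busy0 <- rep(0L, m)
    bexam0 <- rep(0L, m)
    for (j in seq_len(m)) {
      if (t >= 1L && treat[t, j] > 0L) { # slot t-1 (1-based index t)
        i0 <- treat[t, j]
        e0 <- texam[t, j]
        if (is.na(solution$et[i0, e0]) || solution$et[i0, e0] > t) {
          busy0[j] <- i0
          bexam0[j] <- e0
        }
      }
    }
    waiting <- list()
    for (i in seq_len(n)) {
      e <- NA_integer_
      if (p$arrival[i] <= t && (is.na(solution$et[i, 1L]) || solution$et[i, 1L] > t) &&
          !(i %in% busy0)) {
        e <- 1L
        arr_e <- p$arrival[i]
        tbar <- p$tbar1_min[i]
        remn <- model$tt1[i] - delivered_before(i, 1L, t)
      } else if (model$needs2[i] && !is.na(arr2[i]) && arr2[i] <= t &&
                 (is.na(solution$et[i, 2L]) || solution$et[i, 2L] > t) &&
                 !(i %in% busy0)) {
        e <- 2L
        arr_e <- arr2[i]
        tbar <- p$tbar2_min[i]
        remn <- model$tt2[i] - delivered_before(i, 2L, t)
      }
      if (!is.na(e)) {
        waiting[[length(waiting) + 1L]] <- data.frame(
          idx = i, exam = e, arr = arr_e,
          severity = p$severity[i], injury = p$injury[i],
          wait_min = (t - arr_e) * slot,
          remaining_tt_min = remn * slot,
          tbar_min = tbar, stringsAsFactors = FALSE)
      }
    }
    waiting <- if (length(waiting)) do.call(rbind, waiting) else NULL
    # fresh starts at slot t (1-based row t + 1)
    fresh <- list()
    for (j in seq_len(m)) {
      it <- treat[t + 1L, j]
      if (it > 0L && busy0[j] != it) {
        fresh[[length(fresh) + 1L]] <- c(patient = it, exam = texam[t + 1L, j],
                                         physician = j)
      }
    }
    # instants at this slot: completions first, then arrivals
    n_compl <- sum(solution$et == t, na.rm = TRUE)
    arrivals_here <- which(p$arrival == t)
    arr2_here <- which(!is.na(arr2) & arr2 == t)
    instants <- c(rep(list(NULL), n_compl),
                  as.list(arrivals_here), as.list(arr2_here))
    consumed <- rep(FALSE, m)
    fi <- 1L
    for (q in seq_along(instants)) {
      ev_id <- sprintf("t%03d-%d", t, q)
      if (is.null(waiting) || !nrow(waiting)) {
        events[[length(events) + 1L]] <- decision_event(
          numeric(0), matrix(numeric(0), 0, 0), ev_id, schema$id)
        next
      }
      mk_state <- list(t = t, slot_min = slot, waiting = waiting,
                       physicians = data.frame(
                         id = phd$id, seniority = phd$seniority,
                         specialty = phd$specialty, ce = phd$ce,
                         busy_patient = busy0, busy_exam = bexam0,
                         busy_severity = ifelse(busy0 > 0L,
                                                p$severity[pmax(busy0, 1L)], 0L),
                         idle_min = ifelse(busy0 > 0L, 0,
                                           (t - vapply(seq_len(m), last_busy_end,
                                                       integer(1), t = t)) * slot),
                         stringsAsFactors = FALSE))
      cs <- ed_candidate_set(mk_state, schema, exclude = consumed)
      if (!nrow(cs$features)) {
        events[[length(events) + 1L]] <- decision_event(
          numeric(0), matrix(numeric(0), 0, 0), ev_id, schema$id)
        next
      }
      if (fi <= length(fresh)) {
        f <- fresh[[fi]]
        fi <- fi + 1L
        sel <- which(cs$meta$patient == f[["patient"]] &
                       cs$meta$exam == f[["exam"]] &
                       cs$meta$physician == f[["physician"]])
        if (!length(sel)) next
        chosen <- cs$features[sel[1L], ]
        rejected <- cs$features[-sel[1L], , drop = FALSE]
        events[[length(events) + 1L]] <- decision_event(chosen, rejected,
                                                        ev_id, schema$id)
        # the chosen start consumes the physician and seats the patient; a
        # preempted incumbent rejoins the waiting set
        if (busy0[f[["physician"]]] > 0L) {
          ip <- busy0[f[["physician"]]]
          ep <- bexam0[f[["physician"]]]
          arr_e <- if (ep == 1L) p$arrival[ip] else arr2[ip]
          waiting <- rbind(waiting, data.frame(
            idx = ip, exam = ep, arr = arr_e,
            severity = p$severity[ip], injury = p$injury[ip],
            wait_min = (t - arr_e) * slot,
            remaining_tt_min = (if (ep == 1L) model$tt1[ip] else model$tt2[ip]) *
              slot - delivered_before(ip, ep, t) * slot,
            tbar_min = if (ep == 1L) p$tbar1_min[ip] else p$tbar2_min[ip],
            stringsAsFactors = FALSE))
          busy0[f[["physician"]]] <- 0L
          bexam0[f[["physician"]]] <- 0L
        }
        consumed[f[["physician"]]] <- TRUE
        waiting <- waiting[!(waiting$idx == f[["patient"]] &
                               waiting$exam == f[["exam"]]), , drop = FALSE]
      } else {
        # the optimum made no assignment at this instant. For an arrival the
        # chosen option is well-defined -- the arriving patient goes to the
        # wait room. A completion instant with no start has no subject
        # patient (the optimum is holding the queue for reasons encoded in
        # its lookahead, not in the feature vector), so it contributes an
        # empty event: counted, but yielding no pairs.
        subj <- instants[[q]]
        if (is.null(subj) || !(subj %in% waiting$idx)) {
          events[[length(events) + 1L]] <- decision_event(
            numeric(0), matrix(numeric(0), 0, 0), ev_id, schema$id)
          next
        }
        wrow <- which(waiting$idx == subj)[1L]
        sel <- which(cs$meta$patient == waiting$idx[wrow] &
                       cs$meta$exam == waiting$exam[wrow] &
                       cs$meta$physician == 0L)
        if (!length(sel)) next
        chosen <- cs$features[sel[1L], ]
        rejected <- cs$features[-sel[1L], , drop = FALSE]
        events[[length(events) + 1L]] <- decision_event(chosen, rejected,
                                                        ev_id, schema$id)
      }
    }
  }
  events
}
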