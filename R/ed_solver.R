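# Offline ED optimisation: model construction, exact solving, independent
# constraint checking, and a pure-R exhaustive-enumeration oracle.

.lcm2 <- function(a, b) a * b / .gcd2(a, b)
.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)

#' Build the offline ED assignment model
#'
#' Assembles the discrete-horizon optimisation model for a realised scenario:
#' binary assignment indicators `y[i, j, e, t]` (patient i treated by
#' physician j for exam e during slot t) subject to single-patient /
#' single-physician capacity per slot, treatment validity (start before end,
#' second exam after lab return, starts after arrival), work conservation
#' (cumulative delivered work `sum_t y / CE` reaches the nominal treatment
#' time), and derived start/end/wait/LOS/preemption quantities; the objective
#' is the weighted five-component score of [ed_weights()]. The model carries
#' the fully expanded cost tables used by the exact solver.
#'
#' The solver horizon extends past the shift end so every arrival can be
#' completed (an overtime allowance); an instance that still cannot fit is
#' reported infeasible by [solve_offline()].
#'
#' @param scenario an [generate_ed_scenario()] result.
#' @param weights an [ed_weights()] object. The exact solver accrues
#'   excess-wait penalties per slot and therefore requires `exc` linear in the
#'   excess time (the default).
#' @param horizon optional explicit solver horizon in slots.
#' @return An object of class `ed_offline_model`.
#' @export
build_offline_milp <- function(scenario, weights = ed_weights(), horizon = NULL) {
  stopifnot(inherits(scenario, "ed_scenario"), inherits(weights, "ed_weights"))
  p <- scenario$patients
  ph <- scenario$physicians
  n <- nrow(p)
  m <- nrow(ph)
  if (m < 1L) stop_invalid("scenario needs at least one physician")
  if (any(ph$ce != round(ph$ce))) {
    stop_invalid("the exact solver requires integer physician efficiency factors")
  }
  ce <- as.integer(ph$ce)
  scale <- Reduce(.lcm2, ce, accumulate = FALSE)
  slot <- scenario$slot_min
  if (is.null(horizon)) {
    overtime <- if (n) sum((p$tt1 + p$tt2) * max(ce)) + max(c(p$lt, 0L)) + 2L else 0L
    horizon <- scenario$horizon + as.integer(overtime)
  }
  horizon <- as.integer(horizon)
  if (n && any(p$arrival >= horizon)) {
    stop_invalid("all arrivals must fall before the solver horizon")
  }
  alpha <- weights$alpha
  riskCost <- array(0, c(max(n, 1L), m, 2L))
  preCost <- array(0, c(max(n, 1L), 2L))
  waitCost <- array(0, c(max(n, 1L), 2L))
  presCost <- numeric(max(n, 1L))
  for (i in seq_len(n)) {
    presCost[i] <- (alpha[["los"]] + alpha[["crowd"]]) * slot
    for (e in 1:2) {
      preCost[i, e] <- alpha[["preempt"]] * weights$pre(p$severity[i], e)
      waitCost[i, e] <- alpha[["wait"]] * weights$exc(p$severity[i], e, slot)
      for (j in seq_len(m)) {
        riskCost[i, j, e] <- alpha[["risk"]] *
          weights$risk(p$severity[i], p$injury[i], ph$seniority[j],
                       ph$specialty[j], e)
      }
    }
  }
  structure(list(
    scenario = scenario, weights = weights,
    n = n, m = m, T = horizon, slot_min = slot,
    scale = scale, ce = ce, red = as.integer(scale / ce),
    a1 = as.integer(p$arrival), needs2 = as.logical(p$needs_second),
    tt1 = as.integer(p$tt1), tt2 = as.integer(p$tt2),
    full1 = as.integer(p$tt1 * scale), full2 = as.integer(p$tt2 * scale),
    lt = as.integer(p$lt), tb1 = as.integer(p$tbar1), tb2 = as.integer(p$tbar2),
    riskCost = riskCost, preCost = preCost, waitCost = waitCost,
    presCost = presCost,
    variables = sprintf("y[i=1..%d, j=1..%d, e=1..2, t=0..%d]", n, m, horizon - 1L),
    constraints = c(
      "physician_capacity: each physician treats at most one patient per slot",
      "patient_capacity: each patient is treated by at most one physician per slot",
      "treatment_validity: start < end; second exam starts after lab return",
      "arrival: no treatment before the (stage) arrival",
      "work_conservation: cumulative delivered work sum_t y/CE reaches TT",
      "derived: start/end times, WT, LOS, preemption counts, assignment indicators"
    )
  ), class = "ed_offline_model")
}

#' @export
print.ed_offline_model <- function(x, ...) {
  cat("<ed_offline_model>", x$n, "patients x", x$m, "physicians x 2 exams x",
      x$T, "slots\n  variables:", x$variables, "\n  constraints:\n")
  cat(paste0("   - ", x$constraints, collapse = "\n"), "\n")
  invisible(x)
}

#' Solve the offline ED model exactly
#'
#' Computes the optimal schedule by depth-first branch-and-bound over
#' slot-level joint assignment decisions (idling, preemption and physician
#' handoffs included); pruning uses only an admissible lower bound, so the
#' result is exact.
#' The returned solution is verified against an independent constraint checker
#' ([check_schedule()]); any violation raises an error.
#'
#' @param model an [build_offline_milp()] result.
#' @param solver_cfg list; `max_nodes` caps the number of explored states
#'   (default 2e7) -- exceeding it is an error naming the instance size.
#' @return An object of class `schedule_solution`.
#' @export
solve_offline <- function(model, solver_cfg = list(max_nodes = 2e7)) {
  stopifnot(inherits(model, "ed_offline_model"))
  res <- ed_exact_solve(list(
    n = model$n, m = model$m, T = model$T,
    a1 = model$a1, needs2 = model$needs2,
    full1 = model$full1, full2 = model$full2,
    lt = model$lt, tb1 = model$tb1, tb2 = model$tb2,
    red = model$red,
    riskCost = as.numeric(model$riskCost),
    preCost = as.numeric(model$preCost),
    waitCost = as.numeric(model$waitCost),
    presCost = as.numeric(model$presCost),
    max_nodes = solver_cfg$max_nodes %||% 2e7
  ))
  if (!res$feasible) {
    stop_invalid("offline instance infeasible within horizon of ", model$T,
                 " slots: binding constraints are work_conservation and ",
                 "treatment_validity for the late arrivals")
  }
  sol <- .solution_from_assignment(model, res$patient, res$exam,
                                   solver_objective = res$objective,
                                   nodes = res$nodes)
  chk <- check_schedule(sol, model)
  if (!chk$ok) {
    stop_invalid("solver returned a schedule violating: ",
                 paste(chk$violations, collapse = "; "))
  }
  sol
}

# Build a schedule_solution (y array + derived quantities) from the T x m
# per-slot assignment matrices produced by the solver or the oracle.
.solution_from_assignment <- function(model, pat, ex, solver_objective = NULL,
                                      nodes = NA_real_) {
  n <- model$n; m <- model$m; Tn <- model$T
  y <- array(FALSE, c(max(n, 1L), m, 2L, max(Tn, 1L)))
  if (n > 0) {
    for (t in seq_len(Tn)) {
      for (j in seq_len(m)) {
        i <- pat[t, j]
        if (i > 0) y[i, j, ex[t, j], t] <- TRUE
      }
    }
  }
  sol <- .derive_schedule(model, y)
  sol$solver_objective <- solver_objective
  sol$nodes <- nodes
  sol$optimal <- TRUE
  sol
}

# Derived schedule quantities from the assignment indicators.
.derive_schedule <- function(model, y) {
  n <- model$n; m <- model$m; Tn <- model$T
  p <- model$scenario$patients
  slot <- model$slot_min
  st <- et <- matrix(NA_integer_, max(n, 1L), 2L)
  pc <- matrix(0L, max(n, 1L), 2L)
  ac <- array(FALSE, c(max(n, 1L), m, 2L))
  wt <- matrix(NA_real_, max(n, 1L), 2L)
  arrival2 <- rep(NA_integer_, max(n, 1L))
  los <- numeric(max(n, 1L))
  depart <- rep(NA_integer_, max(n, 1L))
  for (i in seq_len(n)) {
    exams <- if (model$needs2[i]) 1:2 else 1L
    for (e in exams) {
      ytj <- y[i, , e, , drop = FALSE] # 1 x m x 1 x T
      active <- apply(ytj, 4, any)
      if (!any(active)) next
      st[i, e] <- which(active)[1L] - 1L
      et[i, e] <- max(which(active)) # end slot index = last active + 1 (0-based)
      starts <- 0L
      for (j in seq_len(m)) {
        yj <- y[i, j, e, ]
        rho <- yj & !c(FALSE, yj[-Tn])
        starts <- starts + sum(rho)
        ac[i, j, e] <- any(rho)
      }
      pc[i, e] <- starts - 1L
    }
    arrival2[i] <- if (model$needs2[i] && !is.na(et[i, 1L])) et[i, 1L] + model$lt[i] else NA_integer_
    wt[i, 1L] <- if (!is.na(st[i, 1L])) (st[i, 1L] - model$a1[i]) * slot else NA_real_
    if (model$needs2[i] && !is.na(st[i, 2L])) {
      wt[i, 2L] <- (st[i, 2L] - arrival2[i]) * slot
    }
    last <- if (model$needs2[i]) et[i, 2L] else et[i, 1L]
    depart[i] <- last
    los[i] <- if (!is.na(last)) (last - model$a1[i]) * slot else NA_real_
  }
  kappa <- integer(Tn)
  for (i in seq_len(n)) {
    if (!is.na(depart[i]) && depart[i] > model$a1[i]) {
      idx <- (model$a1[i] + 1L):depart[i] # slots a1 .. depart-1, 1-based
      kappa[idx] <- kappa[idx] + 1L
    }
  }
  w <- model$weights
  comp <- c(risk = 0, wait = 0, los = 0, crowd = 0, preempt = 0)
  for (i in seq_len(n)) {
    exams <- if (model$needs2[i]) 1:2 else 1L
    for (e in exams) {
      for (j in seq_len(m)) {
        if (ac[i, j, e]) {
          comp[["risk"]] <- comp[["risk"]] +
            w$risk(p$severity[i], p$injury[i],
                   model$scenario$physicians$seniority[j],
                   model$scenario$physicians$specialty[j], e)
        }
      }
      arr_e <- if (e == 1L) model$a1[i] else arrival2[i]
      tb_e <- if (e == 1L) model$tb1[i] else model$tb2[i]
      if (!is.na(st[i, e])) {
        dt_min <- max(0L, st[i, e] - arr_e - tb_e) * slot
        comp[["wait"]] <- comp[["wait"]] + w$exc(p$severity[i], e, dt_min)
        comp[["preempt"]] <- comp[["preempt"]] + pc[i, e] * w$pre(p$severity[i], e)
      }
    }
    comp[["los"]] <- comp[["los"]] + los[i]
  }
  comp[["crowd"]] <- sum(kappa) * slot
  objective <- sum(w$alpha * comp)
  structure(list(
    y = y, st = st, et = et, wt = wt, los = los, pc = pc, ac = ac,
    arrival2 = arrival2, depart = depart, kappa = kappa,
    components = comp, objective = unname(objective),
    model = model
  ), class = "schedule_solution")
}

#' @export
print.schedule_solution <- function(x, ...) {
  cat("<schedule_solution>", x$model$n, "patients; objective",
      signif(x$objective, 6), "\n")
  cat("  components:", paste(names(x$components),
                             signif(x$components, 4), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Independently verify a schedule against the model constraints
#'
#' Re-derives every constraint of the offline model directly from the stored
#' assignment indicators: per-slot physician and patient capacity, treatment
#' validity (start before end, second exam after the lab returns, no
#' treatment before arrival), work conservation (`TT <= sum_t y/CE < TT +
#' max_j 1/CE_j`, i.e. the exam is fully delivered with at most the final
#' slot's overshoot), the derived wait/LOS/preemption/assignment quantities,
#' and the objective value recomputed from scratch.
#'
#' @param solution a `schedule_solution`.
#' @param model the `ed_offline_model` it solves.
#' @param tol numeric tolerance on the objective recomputation.
#' @return List with `ok` (logical) and `violations` (character).
#' @export
check_schedule <- function(solution, model, tol = 1e-6) {
  stopifnot(inherits(solution, "schedule_solution"),
            inherits(model, "ed_offline_model"))
  y <- solution$y
  n <- model$n; m <- model$m; Tn <- model$T
  v <- character(0)
  if (n == 0) return(list(ok = TRUE, violations = v))
  for (t in seq_len(Tn)) {
    for (j in seq_len(m)) {
      if (sum(y[, j, , t]) > 1) v <- c(v, sprintf("physician_capacity at j=%d t=%d", j, t - 1L))
    }
    for (i in seq_len(n)) {
      if (sum(y[i, , , t]) > 1) v <- c(v, sprintf("patient_capacity at i=%d t=%d", i, t - 1L))
    }
  }
  for (i in seq_len(n)) {
    exams <- if (model$needs2[i]) 1:2 else 1L
    for (e in exams) {
      active <- apply(y[i, , e, , drop = FALSE], 4, any)
      if (!any(active)) {
        v <- c(v, sprintf("exam %d of patient %d never scheduled", e, i))
        next
      }
      st <- which(active)[1L] - 1L
      et <- max(which(active))
      if (!(st < et)) v <- c(v, sprintf("treatment_validity (start<end) i=%d e=%d", i, e))
      if (e == 1L) {
        if (st < model$a1[i]) v <- c(v, sprintf("arrival violated i=%d e=1", i))
      } else {
        act1 <- apply(y[i, , 1L, , drop = FALSE], 4, any)
        if (any(act1)) {
          et1 <- max(which(act1))
          if (st < et1) v <- c(v, sprintf("second exam before first ends i=%d", i))
          if (st < et1 + model$lt[i]) {
            v <- c(v, sprintf("second exam before lab return i=%d", i))
          }
        }
      }
      delivered <- 0
      for (j in seq_len(m)) delivered <- delivered + sum(y[i, j, e, ]) / model$ce[j]
      tt <- if (e == 1L) model$tt1[i] else model$tt2[i]
      if (delivered < tt - 1e-9) {
        v <- c(v, sprintf("work_conservation under-delivered i=%d e=%d", i, e))
      }
      if (delivered >= tt + max(1 / model$ce)) {
        v <- c(v, sprintf("work_conservation over-delivered i=%d e=%d", i, e))
      }
      starts <- 0L
      for (j in seq_len(m)) {
        yj <- y[i, j, e, ]
        starts <- starts + sum(yj & !c(FALSE, yj[-Tn]))
      }
      if (starts - 1L != solution$pc[i, e]) {
        v <- c(v, sprintf("preemption count mismatch i=%d e=%d", i, e))
      }
    }
  }
  rederived <- .derive_schedule(model, y)
  if (abs(rederived$objective - solution$objective) > tol) {
    v <- c(v, "objective not recomputable from assignment indicators")
  }
  if (!is.null(solution$solver_objective) &&
      abs(solution$solver_objective - rederived$objective) > max(tol, 1e-6 * abs(rederived$objective))) {
    v <- c(v, sprintf("solver objective %.8g != recomputed %.8g",
                      solution$solver_objective, rederived$objective))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Branch-and-bound enumeration oracle for small ED instances
#'
#' Independent pure-R depth-first search over every slot-level joint
#' assignment sequence (idling, preemption and physician handoffs included),
#' used as the ground-truth optimum against which the exact solver is
#' validated. Exactness is preserved by pruning only with an admissible lower
#' bound: the cost already accrued plus presence costs over each patient's
#' minimum achievable remaining stay and, for untouched examinations, the
#' cheapest possible physician risk. Refuses instances whose search would
#' exceed `max_nodes` explored decision nodes.
#'
#' @param scenario an `ed_scenario` (small: a few patients/physicians).
#' @param weights an [ed_weights()].
#' @param max_nodes node budget (default 2e6).
#' @param horizon optional explicit horizon in slots.
#' @return A `schedule_solution` (with `$objective` the exact optimum).
#' @export
brute_force_schedule <- function(scenario, weights = ed_weights(),
                                 max_nodes = 2e6, horizon = NULL) {
  model <- build_offline_milp(scenario, weights, horizon = horizon)
  n <- model$n; m <- model$m; Tn <- model$T
  if (n == 0) {
    return(.solution_from_assignment(model,
                                     matrix(0L, max(Tn, 1L), m),
                                     matrix(0L, max(Tn, 1L), m)))
  }
  nodes <- 0
  presC <- model$presCost; a1 <- model$a1
  full1 <- model$full1; full2 <- model$full2
  waitC <- model$waitCost; preC <- model$preCost; riskC <- model$riskCost
  red <- model$red; lt <- model$lt; tb1 <- model$tb1; tb2 <- model$tb2
  needs2 <- model$needs2
  maxred <- max(red)
  minrisk <- apply(riskC, c(1, 3), min) # cheapest physician per (patient, exam)

  best_cost <- Inf
  best_path <- NULL

  all_actions <- function(elig) {
    # all injective maps physicians -> {0} + elig; denser assignments first so
    # a good incumbent is found early
    acts <- list(integer(m))
    for (j in seq_len(m)) {
      nxt <- list()
      for (a in acts) {
        for (i in elig) {
          if (!(i %in% a[seq_len(j - 1L)])) {
            a[j] <- i
            nxt[[length(nxt) + 1L]] <- a
          }
        }
        a[j] <- 0L
        nxt[[length(nxt) + 1L]] <- a
      }
      acts <- nxt
    }
    acts
  }

  # admissible lower bound on the cost still to come
  lower_bound <- function(t, ph, rem, aux, mask1, mask2) {
    lb <- 0
    for (i in seq_len(n)) {
      if (ph[i] == 3L) next
      slots_left <- if (ph[i] == 0L) {
        ceiling(rem[i] / maxred) +
          if (needs2[i]) lt[i] + ceiling(full2[i] / maxred) else 0L
      } else if (ph[i] == 1L) {
        max(aux[i] - t, 0L) + ceiling(rem[i] / maxred)
      } else {
        ceiling(rem[i] / maxred)
      }
      lb <- lb + presC[i] * slots_left
      if (ph[i] == 0L && mask1[i] == 0L) lb <- lb + minrisk[i, 1L]
      if (needs2[i] && ph[i] != 3L && mask2[i] == 0L) lb <- lb + minrisk[i, 2L]
    }
    lb
  }

  rec <- function(t, ph, rem, aux, prevj, mask1, mask2, accrued, path) {
    lab <- ph == 1L & aux <= t
    ph[lab] <- 2L
    if (all(ph == 3L)) {
      if (accrued < best_cost - 1e-12) {
        best_cost <<- accrued
        best_path <<- path
      }
      return(invisible(NULL))
    }
    if (t >= Tn) return(invisible(NULL))
    if (accrued + lower_bound(t, ph, rem, aux, mask1, mask2) >= best_cost - 1e-12) {
      return(invisible(NULL))
    }
    nodes <<- nodes + 1
    if (nodes > max_nodes) {
      stop_invalid("brute-force oracle refuses: exceeded ", max_nodes,
                   " nodes on an instance with ", n, " patients, ", m,
                   " physicians, ", Tn, " slots")
    }
    base <- sum(presC[ph < 3L & t >= a1])
    elig <- which((ph == 0L & t >= a1) | ph == 2L)
    for (act in all_actions(elig)) {
      ph2 <- ph; rem2 <- rem; aux2 <- aux; m1 <- mask1; m2 <- mask2
      prev2 <- rep(0L, n)
      cost <- 0
      exrec <- integer(m)
      for (j in seq_len(m)) {
        i <- act[j]
        if (i == 0L) next
        e <- if (ph2[i] == 0L) 1L else 2L
        exrec[j] <- e
        full <- if (e == 1L) full1[i] else full2[i]
        if (prevj[i] != j) {
          if (rem2[i] < full) cost <- cost + preC[i, e]
          bit <- bitwShiftL(1L, j - 1L)
          msk <- if (e == 1L) m1[i] else m2[i]
          if (bitwAnd(msk, bit) == 0L) {
            cost <- cost + riskC[i, j, e]
            if (e == 1L) m1[i] <- bitwOr(m1[i], bit) else m2[i] <- bitwOr(m2[i], bit)
          }
        }
        rem2[i] <- rem2[i] - red[j]
        if (rem2[i] <= 0L) {
          if (e == 1L) {
            if (needs2[i]) {
              ph2[i] <- 1L; aux2[i] <- t + 1L + lt[i]; rem2[i] <- full2[i]
            } else ph2[i] <- 3L
          } else ph2[i] <- 3L
        } else prev2[i] <- j
      }
      for (i in seq_len(n)) {
        if (i %in% act) next
        if (ph2[i] == 0L && t >= a1[i] && rem2[i] == full1[i] && t >= a1[i] + tb1[i]) {
          cost <- cost + waitC[i, 1L]
        } else if (ph2[i] == 2L && rem2[i] == full2[i] && t >= aux2[i] + tb2[i]) {
          cost <- cost + waitC[i, 2L]
        }
      }
      rec(t + 1L, ph2, rem2, aux2, prev2, m1, m2,
          accrued + base + cost, c(path, list(cbind(act, exrec))))
    }
    invisible(NULL)
  }

  rec(0L, rep(0L, n), full1, rep(0L, n), rep(0L, n), rep(0L, n), rep(0L, n),
      0, list())
  if (!is.finite(best_cost)) {
    stop_invalid("brute-force oracle: instance infeasible within the horizon")
  }
  pat <- matrix(0L, Tn, m); ex <- matrix(0L, Tn, m)
  for (k in seq_along(best_path)) {
    amat <- best_path[[k]]
    t <- k - 1L
    if (t >= Tn) break
    for (j in seq_len(m)) {
      if (amat[j, 1L] > 0L) {
        pat[t + 1L, j] <- amat[j, 1L]
        ex[t + 1L, j] <- amat[j, 2L]
      }
    }
  }
  sol <- .solution_from_assignment(model, pat, ex, solver_objective = best_cost,
                                   nodes = nodes)
  sol
}
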