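# End-to-end experiment driver: scenario generation -> offline optimisation
# (exact search or MCTS) -> training-pair extraction -> comparator training ->
# policy evaluation -> statistics and report tables. One master seed derives
# every sub-seed, so a rerun is byte-identical.

#' ED experiment configuration
#'
#' @param n_train number of small offline-solved training scenarios.
#' @param n_eval number of evaluation shift simulations per policy.
#' @param flow `"normal"` (rate multiplier 1) or `"heavy"` (2; twice the
#'   expected patients).
#' @param train_cfg scenario config for offline training scenarios.
#' @param eval_cfg scenario config for evaluation shifts.
#' @param weights an [ed_weights()].
#' @param hidden,epochs,lr,batch_size comparator hyperparameters.
#' @param n_candidates number of candidate comparators trained (the first on
#'   all pairs, the rest on random scenario subsets); the deployed model is
#'   chosen by simulated validation shifts. The margin of an imitated policy
#'   over the baseline is sensitive to the training draw, and validation
#'   performance tracks deployment performance closely, so selection over a
#'   few candidates stabilises the pipeline.
#' @param subset_frac fraction of training scenarios per subset candidate.
#' @param n_val number of validation shifts (a seed stream separate from the
#'   evaluation shifts).
#' @param seed master seed.
#' @return A list of class `experiment_config`.
#' @export
ed_experiment_config <- function(n_train = 260L, n_eval = 100L,
                                 flow = c("normal", "heavy"),
                                 train_cfg = NULL, eval_cfg = NULL,
                                 weights = ed_weights(),
                                 hidden = c(32L, 32L), epochs = 100L,
                                 lr = 1e-3, batch_size = 64L,
                                 n_candidates = 4L, subset_frac = 0.7,
                                 n_val = 10L, seed = 1L) {
  flow <- match.arg(flow)
  mult <- if (flow == "heavy") 2 else 1
  structure(list(
    domain = "ed", n_train = as.integer(n_train), n_eval = as.integer(n_eval),
    flow = flow,
    train_cfg = train_cfg %||% ed_training_config(flow = mult),
    eval_cfg = eval_cfg %||% ed_config(flow = mult),
    weights = weights,
    hidden = hidden, epochs = as.integer(epochs), lr = lr,
    batch_size = as.integer(batch_size),
    n_candidates = as.integer(n_candidates), subset_frac = subset_frac,
    n_val = as.integer(n_val), solver_max_nodes = 2e6,
    seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Radiology experiment configuration
#'
#' @param n_train number of MCTS-searched training scenarios.
#' @param budget MCTS simulations per decision.
#' @param n_eval number of evaluation simulations per policy.
#' @param train_cfg scenario config for training scenarios.
#' @param eval_cfg scenario config for evaluation scenarios.
#' @param k_sweep pool caps at which the learned policy is additionally
#'   evaluated.
#' @param hidden,epochs,lr,batch_size comparator hyperparameters.
#' @param n_candidates,subset_frac,n_val model-selection settings: number of
#'   candidate comparators (first on all pairs, rest on scenario subsets),
#'   subset fraction, and the number of simulated validation reading rooms
#'   used to pick the deployed model (stream separate from evaluation).
#' @param seed master seed.
#' @return A list of class `experiment_config`.
#' @export
rad_experiment_config <- function(n_train = 12L, budget = 48L, n_eval = 100L,
                                  train_cfg = NULL, eval_cfg = NULL,
                                  k_sweep = c(10L, 5L, 2L),
                                  hidden = c(32L, 32L), epochs = 150L,
                                  lr = 1e-3, batch_size = 64L,
                                  n_candidates = 4L, subset_frac = 0.7,
                                  n_val = 10L, seed = 1L) {
  structure(list(
    domain = "radiology", n_train = as.integer(n_train),
    budget = as.integer(budget), n_eval = as.integer(n_eval),
    train_cfg = train_cfg %||% rad_training_config(),
    eval_cfg = eval_cfg %||% rad_config(),
    k_sweep = as.integer(k_sweep),
    hidden = hidden, epochs = as.integer(epochs), lr = lr,
    batch_size = as.integer(batch_size),
    n_candidates = as.integer(n_candidates), subset_frac = subset_frac,
    n_val = as.integer(n_val), seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Run the full learning-based assignment pipeline
#'
#' Executes the whole loop for one domain: generate small training scenarios,
#' solve them offline (exact branch-and-bound for the ED; Monte-Carlo tree
#' search for radiology), translate the optimal decisions into preference
#' pairs, train the anti-symmetric comparator, and evaluate the learned
#' online policy against the domain baselines on fresh simulated scenarios.
#' Every stage's randomness derives from the master seed; a rerun reproduces
#' the per-simulation score table exactly.
#'
#' @param config an [ed_experiment_config()] or [rad_experiment_config()].
#' @param progress print stage progress (default FALSE).
#' @return An object of class `experiment_result`: per-simulation `scores`,
#'   the trained `model`, the preference `pairs`, stage seeds, and the paired
#'   statistics (`test`).
#' @export
run_lba_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message(...)
  if (config$domain == "ed") .run_ed_pipeline(config, say)
  else .run_rad_pipeline(config, say)
}

.run_ed_pipeline <- function(config, say) {
  seed <- config$seed
  say("stage 1/4: generating and solving ", config$n_train, " training scenarios")
  scenario_events <- list()
  solved <- 0L
  for (i in seq_len(config$n_train)) {
    scn <- generate_ed_scenario(config$train_cfg, seed = derive_seed(seed, "ed-train", i))
    if (nrow(scn$patients) == 0L) next
    sol <- tryCatch(
      solve_offline(build_offline_milp(scn, config$weights),
                    solver_cfg = list(max_nodes = config$solver_max_nodes %||% 2e7)),
      error = function(e) NULL)
    if (is.null(sol)) next
    solved <- solved + 1L
    scenario_events[[length(scenario_events) + 1L]] <- extract_decision_events(sol)
  }
  events <- unlist(scenario_events, recursive = FALSE)
  say("stage 2/4: building pairs from ", length(events), " decision events")
  pairs <- suppressWarnings(build_training_pairs(events))
  say("stage 3/4: training ", config$n_candidates,
      " candidate comparators (model selection by simulated validation)")
  ncand <- max(1L, config$n_candidates %||% 1L)
  candidates <- vector("list", ncand)
  for (k in seq_len(ncand)) {
    pk <- if (k == 1L) pairs else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, "ed-subset", k))
      sub <- sample(length(scenario_events),
                    max(1L, round(config$subset_frac * length(scenario_events))))
      .Random.seed_restore(old)
      suppressWarnings(build_training_pairs(
        unlist(scenario_events[sub], recursive = FALSE)))
    }
    candidates[[k]] <- train_comparator(pk, hidden = config$hidden,
                                        lr = config$lr,
                                        epochs = config$epochs,
                                        batch_size = config$batch_size,
                                        seed = derive_seed(seed, "ed-train-model", k))
  }
  model <- candidates[[1L]]
  if (ncand > 1L && config$n_val > 0L) {
    val <- vapply(candidates, function(mod) {
      mean(vapply(seq_len(config$n_val), function(s) {
        sce <- generate_ed_scenario(config$eval_cfg,
                                    seed = derive_seed(seed, "ed-val", s))
        simulate_shift("lba", sce, config$weights,
                       seed = derive_seed(seed, "ed-val-sim", s),
                       model = mod)$objective
      }, numeric(1)))
    }, numeric(1))
    model <- candidates[[which.min(val)]]
    say("  validation scores: ", paste(signif(val, 5), collapse = " "),
        " -> candidate ", which.min(val))
  }
  say("stage 4/4: evaluating on ", config$n_eval, " simulated shifts")
  rows <- list()
  for (i in seq_len(config$n_eval)) {
    scn <- generate_ed_scenario(config$eval_cfg, seed = derive_seed(seed, "ed-eval", i))
    for (pol in c("fcfswu", "lba")) {
      ms <- simulate_shift(pol, scn, config$weights,
                           seed = derive_seed(seed, paste0("ed-sim-", pol), i),
                           model = if (pol == "lba") model else NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        sim = i, policy = pol, objective = ms$objective,
        risk = ms$components[["risk"]], wait_pen = ms$components[["wait"]],
        los = ms$components[["los"]], crowd = ms$components[["crowd"]],
        preempt_pen = ms$components[["preempt"]],
        preempt_count = ms$pre_count,
        mean_wait_min = mean(c(ms$per_patient$wt1_min, ms$per_patient$wt2_min),
                             na.rm = TRUE),
        n_patients = nrow(ms$per_patient))
    }
  }
  scores <- do.call(rbind, rows)
  a <- scores$objective[scores$policy == "lba"]
  b <- scores$objective[scores$policy == "fcfswu"]
  structure(list(domain = "ed", config = config, scores = scores,
                 model = model, pairs = pairs, n_solved = solved,
                 test = paired_compare(a, b),
                 mean_scores = c(lba = mean(a), fcfswu = mean(b))),
            class = "experiment_result")
}

.run_rad_pipeline <- function(config, say) {
  seed <- config$seed
  say("stage 1/4: tree search on ", config$n_train, " training scenarios")
  scenario_events <- list()
  for (i in seq_len(config$n_train)) {
    scn <- generate_radiology_scenario(config$train_cfg,
                                       seed = derive_seed(seed, "rad-train", i))
    res <- mcts_search(scn, budget = config$budget,
                       seed = derive_seed(seed, "rad-mcts", i))
    scenario_events[[length(scenario_events) + 1L]] <- res$events
  }
  events <- unlist(scenario_events, recursive = FALSE)
  say("stage 2/4: building pairs from ", length(events), " decision events")
  pairs <- suppressWarnings(build_training_pairs(events))
  say("stage 3/4: training ", config$n_candidates,
      " candidate comparators (model selection by simulated validation)")
  ncand <- max(1L, config$n_candidates %||% 1L)
  candidates <- vector("list", ncand)
  for (k in seq_len(ncand)) {
    pk <- if (k == 1L) pairs else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, "rad-subset", k))
      sub <- sample(length(scenario_events),
                    max(1L, round(config$subset_frac * length(scenario_events))))
      .Random.seed_restore(old)
      suppressWarnings(build_training_pairs(
        unlist(scenario_events[sub], recursive = FALSE)))
    }
    candidates[[k]] <- train_comparator(pk, hidden = config$hidden,
                                        lr = config$lr,
                                        epochs = config$epochs,
                                        batch_size = config$batch_size,
                                        seed = derive_seed(seed, "rad-train-model", k))
  }
  model <- candidates[[1L]]
  if (ncand > 1L && config$n_val > 0L) {
    kd <- config$k_sweep[1L]
    val <- vapply(candidates, function(mod) {
      mean(vapply(seq_len(config$n_val), function(s) {
        sce <- generate_radiology_scenario(config$eval_cfg,
                                           seed = derive_seed(seed, "rad-val", s))
        simulate_reading_room("dnn", sce,
                              seed = derive_seed(seed, "rad-val-sim", s),
                              k = kd, model = mod)$report$total_loss
      }, numeric(1)))
    }, numeric(1))
    model <- candidates[[which.min(val)]]
    say("  validation losses: ", paste(signif(val, 5), collapse = " "),
        " -> candidate ", which.min(val))
  }
  say("stage 4/4: evaluating on ", config$n_eval, " simulations per policy")
  rows <- list()
  ks <- config$k_sweep
  for (i in seq_len(config$n_eval)) {
    scn <- generate_radiology_scenario(config$eval_cfg,
                                       seed = derive_seed(seed, "rad-eval", i))
    runs <- list(
      naive = simulate_reading_room("naive", scn,
                                    seed = derive_seed(seed, "rad-sim-naive", i)),
      h = simulate_reading_room("h", scn,
                                seed = derive_seed(seed, "rad-sim-h", i))
    )
    for (k in ks) {
      runs[[paste0("dnn_k", k)]] <- simulate_reading_room(
        "dnn", scn, seed = derive_seed(seed, paste0("rad-sim-dnn", k), i),
        k = k, model = model)
    }
    for (nm in names(runs)) {
      r <- runs[[nm]]
      bins <- r$report$bins
      rows[[length(rows) + 1L]] <- data.frame(
        sim = i, policy = nm, total_loss = r$report$total_loss,
        pool_mean = r$pool_mean, pool_sd = r$pool_sd, pool_max = r$pool_max,
        t(bins))
    }
  }
  scores <- do.call(rbind, rows)
  k_def <- paste0("dnn_k", ks[1L])
  groups <- list(dnn = scores$total_loss[scores$policy == k_def],
                 naive = scores$total_loss[scores$policy == "naive"],
                 h = scores$total_loss[scores$policy == "h"])
  structure(list(domain = "radiology", config = config, scores = scores,
                 model = model, pairs = pairs,
                 test = paired_compare(groups = groups),
                 mean_scores = vapply(groups, mean, numeric(1)),
                 k_means = vapply(ks, function(k) {
                   mean(scores$total_loss[scores$policy == paste0("dnn_k", k)])
                 }, numeric(1)) |> stats::setNames(paste0("k", ks))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$domain, "domain\n  mean scores:",
      paste(names(x$mean_scores), signif(x$mean_scores, 5), sep = "=",
            collapse = "  "), "\n")
  if (!is.null(x$k_means)) {
    cat("  learned policy by pool cap:",
        paste(names(x$k_means), signif(x$k_means, 5), sep = "=", collapse = "  "),
        "\n")
  }
  print(x$test)
  invisible(x)
}

#' Paired statistical comparison of policy scores
#'
#' Two modes. With `a` and `b`: a paired-samples t-test (identical lists give
#' `t = 0, p = 1`; a non-zero constant difference is a degenerate exact case
#' reported as `p = 0`). With `groups` (a named list of 3 or more
#' equal-length score vectors from the same simulations): a one-way ANOVA
#' followed by all pairwise paired t-tests with Bonferroni correction.
#'
#' @param a,b equal-length paired score vectors.
#' @param groups named list of 3+ equal-length score vectors.
#' @return An object of class `paired_comparison`.
#' @export
paired_compare <- function(a = NULL, b = NULL, groups = NULL) {
  if (!is.null(groups)) {
    stopifnot(length(groups) >= 3, length(unique(lengths(groups))) == 1)
    if (lengths(groups)[1] < 2) stop_invalid("need at least 2 paired observations")
    long <- data.frame(
      score = unlist(groups, use.names = FALSE),
      policy = factor(rep(names(groups), lengths(groups))))
    fit <- aov(score ~ policy, data = long)
    an <- summary(fit)[[1]]
    nms <- names(groups)
    pw <- list()
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (i < j) {
          cmp <- paired_compare(groups[[i]], groups[[j]])
          pw[[paste(nms[i], "vs", nms[j])]] <- c(t = cmp$t, p = cmp$p,
                                                 mean_diff = cmp$mean_diff)
        }
      }
    }
    praw <- vapply(pw, function(z) z[["p"]], numeric(1))
    padj <- p.adjust(praw, method = "bonferroni")
    for (nm in names(pw)) pw[[nm]][["p_bonferroni"]] <- padj[[nm]]
    return(structure(list(mode = "anova",
                          anova_F = an[["F value"]][1],
                          anova_p = an[["Pr(>F)"]][1],
                          pairwise = pw), class = "paired_comparison"))
  }
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (length(a) < 2) stop_invalid("need at least 2 paired observations")
  d <- a - b
  if (sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      out <- list(mode = "paired_t", t = 0, p = 1, mean_diff = 0,
                  direction = "equal", n = length(a))
    } else {
      out <- list(mode = "paired_t", t = sign(mean(d)) * Inf, p = 0,
                  mean_diff = mean(d),
                  direction = if (mean(d) < 0) "a_lower" else "a_higher",
                  n = length(a))
    }
    return(structure(out, class = "paired_comparison"))
  }
  tt <- t.test(a, b, paired = TRUE)
  structure(list(mode = "paired_t",
                 t = unname(tt$statistic), p = tt$p.value,
                 mean_diff = mean(d),
                 direction = if (mean(d) < 0) "a_lower" else
                   if (mean(d) > 0) "a_higher" else "equal",
                 n = length(a)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$mode == "paired_t") {
    cat("  paired t-test: t =", signif(x$t, 4), " p =", signif(x$p, 4),
        " mean diff =", signif(x$mean_diff, 4), paste0("(", x$direction, ")"),
        "\n")
  } else {
    cat("  one-way ANOVA: F =", signif(x$anova_F, 4), " p =",
        signif(x$anova_p, 4), "\n")
    for (nm in names(x$pairwise)) {
      z <- x$pairwise[[nm]]
      cat("   ", nm, ": p_bonf =", signif(z[["p_bonferroni"]], 4),
          " mean diff =", signif(z[["mean_diff"]], 4), "\n")
    }
  }
  invisible(x)
}

#' Format experiment results as report tables
#'
#' For the ED: the marginal-improvement table over the five objective
#' components (positive = the learned policy improves on the baseline). For
#' radiology: the lateness-distribution table (five bins by policy, in
#' percent) and pool-size statistics. Optionally writes CSV files.
#'
#' @param result an [run_lba_pipeline()] result (or one with zero rows).
#' @param dir optional output directory for CSV files.
#' @return A named list of data frames.
#' @export
report_tables <- function(result, dir = NULL) {
  out <- list()
  sc <- result$scores
  if (identical(result$domain, "ed")) {
    crits <- c(risk = "risk", wait_times = "mean_wait_min", length_of_stay = "los",
               crowdedness = "crowd", interruptions = "preempt_pen")
    tab <- data.frame(criterion = names(crits), fcfswu = NA_real_,
                      lba = NA_real_, improvement_pct = NA_real_)
    if (!is.null(sc) && nrow(sc)) {
      for (r in seq_along(crits)) {
        fb <- mean(sc[sc$policy == "fcfswu", crits[r]])
        lb <- mean(sc[sc$policy == "lba", crits[r]])
        tab$fcfswu[r] <- fb
        tab$lba[r] <- lb
        tab$improvement_pct[r] <- if (abs(fb) > 1e-12) 100 * (fb - lb) / fb else 0
      }
    }
    out$marginal_improvement <- tab
  } else {
    bins <- .LATENESS_BINS
    pols <- if (!is.null(sc) && nrow(sc)) unique(sc$policy) else character(0)
    tab <- data.frame(bin = bins)
    pstat <- data.frame(policy = pols,
                        pool_mean = rep(NA_real_, length(pols)),
                        pool_sd = rep(NA_real_, length(pols)))
    for (p in pols) {
      rowsp <- sc[sc$policy == p, , drop = FALSE]
      tab[[p]] <- round(100 * colMeans(rowsp[, bins, drop = FALSE]), 1)
      pstat[pstat$policy == p, "pool_mean"] <- mean(rowsp$pool_mean)
      pstat[pstat$policy == p, "pool_sd"] <- mean(rowsp$pool_sd)
    }
    out$lateness_distribution <- tab
    out$pool_sizes <- pstat
  }
  if (!is.null(result$scores)) out$raw_scores <- result$scores
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  out
}
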