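# Monte-Carlo tree search over exposure decisions, used to approximate the
# optimal (loss-minimising) exposure policy; its committed decisions are
# recorded as decision events for comparator training.
#
# Decision epochs are state-derived: whenever an arrived, unread study is in
# no reader's pool and some reader has room below the cap, an exposure
# decision (which study goes to which reader) must be made. Reader choices
# from their pools are chance nodes (quantal response, re-sampled per
# simulation; open-loop averaging). Rollouts follow an
# earliest-deadline-first exposure heuristic.

# advance a radiology state to completion, consulting `decide` at each
# exposure epoch. decide(state, epoch) returns an index into epoch$actions.
# epoch$actions is a data frame (sid, reader). Returns the final state.
.rad_advance <- function(state, scenario, decide, max_candidates = 4L) {
  R <- length(state$pools)
  repeat {
    # exposure epochs
    repeat {
      pend <- which(state$status == 1L)
      if (length(pend)) {
        inpool <- unique(unlist(state$pools))
        unexp <- setdiff(pend, inpool)
      } else unexp <- integer(0)
      rooms <- which(lengths(state$pools) < state$k)
      if (!length(unexp) || !length(rooms)) break
      unexp <- unexp[order(state$due[unexp])]
      if (length(unexp) > max_candidates) {
        # span the urgency spectrum: the most urgent studies plus the least
        # urgent one, so chosen-vs-rejected pairs contrast deadlines broadly
        unexp <- c(unexp[seq_len(max_candidates - 1L)], unexp[length(unexp)])
      }
      actions <- expand.grid(sid = unexp, reader = rooms,
                             KEEP.OUT.ATTRS = FALSE)
      epoch <- list(actions = actions,
                    labels = paste0("s", actions$sid, "r", actions$reader))
      a <- if (nrow(actions) == 1L) 1L else decide(state, epoch)
      sid <- actions$sid[a]
      j <- actions$reader[a]
      pool <- c(state$pools[[j]], sid)
      state$pools[[j]] <- pool[order(state$due[pool])] # keep pools deadline-ordered
    }
    # idle readers start reading (quantal choice = chance)
    repeat {
      started <- FALSE
      for (j in seq_len(R)) {
        if (state$busy_study[j] > 0L) next
        pool <- state$pools[[j]]
        pool <- pool[state$status[pool] == 1L]
        if (!length(pool)) next
        pr <- choice_probabilities(state$util_s[pool, j])
        sid <- if (length(pool) == 1L) pool else
          pool[sample.int(length(pool), 1L, prob = pr)]
        state$status[sid] <- 2L
        state$reader[sid] <- j
        state$read_start[sid] <- state$now
        rt <- if (state$in_sub[sid, j]) scenario$cfg$nominal_read_min else
          scenario$cfg$rho * scenario$cfg$nominal_read_min
        state$busy_until[j] <- state$now + rt
        state$busy_study[j] <- sid
        state$pools <- lapply(state$pools, function(p) p[p != sid])
        started <- TRUE
      }
      if (!started) break
    }
    if (all(state$status == 3L)) break
    unarr <- which(state$status == 0L)
    t_arr <- if (length(unarr)) min(state$arrival[unarr]) else Inf
    t_done <- min(state$busy_until)
    t_next <- min(t_arr, t_done)
    if (!is.finite(t_next)) break # nothing can progress (should not happen)
    state$now <- t_next
    for (j in which(state$busy_until <= t_next + 1e-9)) {
      sid <- state$busy_study[j]
      state$status[sid] <- 3L
      state$read_end[sid] <- state$busy_until[j]
      state$busy_until[j] <- Inf
      state$busy_study[j] <- 0L
    }
    arriving <- which(state$status == 0L & state$arrival <= t_next + 1e-9)
    if (length(arriving)) state$status[arriving] <- 1L
  }
  state
}

# earliest-deadline-first rollout choice: most urgent study, to a
# subspecialty reader when one has room, else the emptiest pool
.edf_choice <- function(state, epoch) {
  acts <- epoch$actions
  due <- state$due[acts$sid]
  insub <- state$in_sub[cbind(acts$sid, acts$reader)]
  psz <- lengths(state$pools)[acts$reader]
  order(due, !insub, psz)[1L]
}

.new_node <- function() {
  e <- new.env(parent = emptyenv())
  e$N <- 0; e$W <- 0; e$S2 <- 0
  e$children <- list()
  e
}

#' Monte-Carlo tree search over exposure decisions
#'
#' Runs a scenario to completion, making every exposure decision by UCT: at
#' each epoch, `budget` simulations are played out from the current state
#' (tree policy inside the search tree keyed by action labels, open-loop over
#' the stochastic reader choices; earliest-deadline-first rollouts beyond the
#' tree), minimising the total exponential lateness loss. The committed
#' decision at each epoch, together with its rejected alternatives, is
#' recorded as a [decision_event()] on the 7-feature study-reader schema.
#'
#' @param scenario a [generate_radiology_scenario()] result.
#' @param budget simulations per decision (must be positive).
#' @param cfg list: `c` UCT exploration constant (default `sqrt(2)`),
#'   `max_candidates` cap on simultaneously considered unexposed studies
#'   (default 4).
#' @param seed integer seed.
#' @param k pool cap (default from the scenario config).
#' @return List with `events` (list of [decision_event()]), `report` (the
#'   final [lateness_report()]) and `total_loss`.
#' @export
mcts_search <- function(scenario, budget = 50L, cfg = list(), seed = 1L,
                        k = scenario$cfg$k) {
  stopifnot(inherits(scenario, "rad_scenario"))
  if (!is.numeric(budget) || budget < 1) stop_invalid("MCTS budget must be positive")
  cexp <- cfg$c %||% sqrt(2)
  maxc <- cfg$max_candidates %||% 3L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  schema <- rad_schema()
  events <- list()
  ev_ct <- 0L

  real_decide <- function(state, epoch) {
    labels <- epoch$labels
    root <- .new_node()
    # common random numbers across playouts: the chance draws (reader
    # choices) for playout b are seeded identically whichever action the
    # tree explores, so action comparisons are paired
    ev_ct <<- ev_ct + 1L
    po_base <- derive_seed(seed, "playout", ev_ct)
    rng_main <- .Random.seed_save()
    n_play <- max(budget, 2L * length(labels))
    for (b in seq_len(n_play)) {
      set.seed(derive_seed(po_base, "b", b))
      path <- list(root)
      in_tree <- TRUE
      expanded <- FALSE
      at_root <- TRUE
      playout_decide <- function(st, ep) {
        if (!in_tree) return(.edf_choice(st, ep))
        node <- path[[length(path)]]
        labs <- ep$labels
        if (at_root) {
          # root children are visited round-robin and the chance draws of a
          # child's v-th visit are seeded by v, so the means compared at
          # commitment are paired across actions
          at_root <<- FALSE
          idx <- ((b - 1L) %% length(labs)) + 1L
          lab <- labs[idx]
          if (is.null(node$children[[lab]])) node$children[[lab]] <- .new_node()
          child <- node$children[[lab]]
          path[[length(path) + 1L]] <<- child
          set.seed(derive_seed(po_base, "v", child$N + 1L))
          return(idx)
        }
        kids <- node$children
        unexp <- setdiff(labs, names(kids))
        if (length(unexp) && !expanded) {
          lab <- unexp[1L]
          child <- .new_node()
          node$children[[lab]] <- child
          path[[length(path) + 1L]] <<- child
          expanded <<- TRUE
          in_tree <<- FALSE
          return(match(lab, labs))
        }
        avail <- intersect(labs, names(kids))
        if (!length(avail)) {
          in_tree <<- FALSE
          return(.edf_choice(st, ep))
        }
        sdev <- if (node$N > 1) {
          sqrt(max(node$S2 / node$N - (node$W / node$N)^2, 0))
        } else 1
        ucb <- vapply(avail, function(l) {
          ch <- kids[[l]]
          if (ch$N == 0) return(-Inf)
          ch$W / ch$N - cexp * max(sdev, 1e-6) * sqrt(log(node$N) / ch$N)
        }, numeric(1))
        lab <- avail[which.min(ucb)]
        path[[length(path) + 1L]] <<- kids[[lab]]
        return(match(lab, labs))
      }
      final <- .rad_advance(state, scenario, playout_decide, max_candidates = maxc)
      lat <- (final$read_end - final$due) / 60
      r <- log1p(sum(study_loss(lat)))
      for (nd in path) {
        nd$N <- nd$N + 1
        nd$W <- nd$W + r
        nd$S2 <- nd$S2 + r^2
      }
    }
    .Random.seed_restore(rng_main)
    kids <- root$children
    avail <- intersect(labels, names(kids))
    means <- vapply(avail, function(l) {
      if (kids[[l]]$N > 0) kids[[l]]$W / kids[[l]]$N else Inf
    }, numeric(1))
    lab <- avail[which.min(means)]
    a <- match(lab, labels)
    # record the committed decision as a training event
    ch <- featurize_rad_pair(epoch$actions$sid[a], epoch$actions$reader[a], state)
    rej <- lapply(setdiff(seq_along(labels), a), function(r) {
      featurize_rad_pair(epoch$actions$sid[r], epoch$actions$reader[r], state)
    })
    events[[length(events) + 1L]] <<- decision_event(
      ch, rej, sprintf("mcts-%03d", ev_ct), schema$id)
    a
  }

  state <- rad_init_state(scenario, k = k)
  final <- .rad_advance(state, scenario, real_decide, max_candidates = maxc)
  lat <- (final$read_end - final$due) / 60
  list(events = events,
       report = lateness_report(lat, ids = seq_len(final$n)),
       total_loss = sum(study_loss(lat)),
       reading_order = order(final$read_start),
       studies = as_rad_studies(final))
}
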