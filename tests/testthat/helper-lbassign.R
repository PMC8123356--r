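# Shared fixture builders: hand-constructed scenarios and comparators with
# known structure, built in code at test time.

# An ED scenario from explicit patient rows (times in minutes).
make_ed_scenario <- function(patients, physicians = ed_physicians(2L),
                             shift_min = 120, slot_min = 5) {
  n <- nrow(patients)
  defaults <- data.frame(
    id = paste0("p", seq_len(max(n, 1L)))[seq_len(n)],
    arrival_min = 0, severity = 3L, injury = "internal",
    needs_second = FALSE, tt1_min = 20, tt2_min = 0, lt_min = 0,
    stringsAsFactors = FALSE
  )
  for (nm in names(patients)) defaults[[nm]] <- patients[[nm]]
  p <- defaults
  p$tt2_min <- ifelse(p$needs_second, p$tt2_min, 0)
  p$lt_min <- ifelse(p$needs_second, p$lt_min, 0)
  wb <- ed_config()$wait_bounds_min
  p$tbar1_min <- wb[p$severity]
  p$tbar2_min <- wb[p$severity]
  p$arrival <- as.integer(floor(p$arrival_min / slot_min))
  p$tt1 <- pmax(1L, as.integer(ceiling(p$tt1_min / slot_min)))
  p$tt2 <- ifelse(p$needs_second, pmax(1L, as.integer(ceiling(p$tt2_min / slot_min))), 0L)
  p$lt <- as.integer(ceiling(p$lt_min / slot_min))
  p$tbar1 <- as.integer(ceiling(p$tbar1_min / slot_min))
  p$tbar2 <- as.integer(ceiling(p$tbar2_min / slot_min))
  structure(list(patients = p, physicians = physicians,
                 horizon = as.integer(ceiling(shift_min / slot_min)),
                 slot_min = slot_min, cfg = ed_config(), seed = 0L),
            class = "ed_scenario")
}

# Tiny random ED instances for solver-vs-oracle batteries.
tiny_ed_config <- function() {
  ed_config(shift_min = 40, slot_min = 5, rates_per_hour = c(3, 3),
            physicians = ed_physicians(2L), max_patients = 3L,
            tt1_range = c(5, 15), tt2_range = c(5, 10), lt_range = c(5, 15),
            second_exam_prob = 0.5)
}

# An ED decision state for policy tests.
make_ed_state <- function(waiting, physicians, t = 10L, slot_min = 5) {
  wdef <- data.frame(idx = seq_len(nrow(waiting)), exam = 1L, arr = 0L,
                     severity = 3L, injury = "internal", wait_min = 10,
                     remaining_tt_min = 20, tbar_min = 30,
                     stringsAsFactors = FALSE)
  for (nm in names(waiting)) wdef[[nm]] <- waiting[[nm]]
  pdef <- data.frame(id = paste0("c", seq_len(nrow(physicians))),
                     seniority = "attending", specialty = NA_character_,
                     ce = 1L, busy_patient = 0L, busy_exam = 0L,
                     busy_severity = 0L, idle_min = 10,
                     stringsAsFactors = FALSE)
  for (nm in names(physicians)) pdef[[nm]] <- physicians[[nm]]
  list(t = t, slot_min = slot_min, waiting = wdef, physicians = pdef)
}

# A radiology scenario from explicit study rows (times in minutes).
make_rad_scenario <- function(studies, subspec, cfg = rad_config()) {
  n <- nrow(studies)
  sdef <- data.frame(id = seq_len(n), M = "CT", B = "head",
                     arrival = 0, deadline_min = 60, stringsAsFactors = FALSE)
  for (nm in names(studies)) sdef[[nm]] <- studies[[nm]]
  sdef$type <- paste(sdef$M, sdef$B, sep = "|")
  sdef$due <- sdef$arrival + sdef$deadline_min
  utility <- lapply(subspec, function(ss) {
    u <- stats::setNames(rep(0.02, length(cfg$types)), cfg$types)
    u[ss] <- 0.2
    u / sum(u)
  })
  structure(list(studies = sdef, subspec = subspec, utility = utility,
                 cfg = cfg, seed = 0L), class = "rad_scenario")
}

# A comparator whose score is a known monotone function of one feature:
# single tanh unit wired to feature `idx`, so C(x, y) increases with
# (x[idx] - y[idx]). Transitive by construction.
linear_feature_comparator <- function(input_dim, idx, slope = 5) {
  m <- comparator(input_dim, hidden = 1L, seed = 1L)
  W <- matrix(0, 1L, input_dim)
  W[1L, idx] <- 1
  m$layers[[1L]]$W11 <- W * 0.2
  m$layers[[1L]]$W12 <- W * 0 # no cross-talk: towers see their own input
  m$layers[[1L]]$b <- 0
  m$w_out <- slope
  m
}
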