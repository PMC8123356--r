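# Combined patient-physician feature vector for the ED comparator.

#' ED feature schema
#'
#' Fixed-order combined patient-physician feature vector: severity (1/5..5/5),
#' injury one-hot, remaining treatment time (min), wait time so far (min),
#' remaining time until the triage wait bound (min), physician seniority
#' (1/4..4/4), specialization one-hot, status (0 if idle, else the severity of
#' the patient under treatment) and idle time (min). The wait-room dummy
#' physician has its whole physician sub-vector zeroed.
#'
#' @param injuries character vector of injury types (defines the one-hot
#'   blocks).
#' @return A list of class `ed_schema` with `id`, `injuries`, `length` and
#'   `feature_names`.
#' @export
ed_schema <- function(injuries = ed_config()$injuries) {
  k <- length(injuries)
  structure(list(
    id = paste0("ed/", paste(injuries, collapse = "+")),
    injuries = injuries,
    length = 7L + 2L * k,
    feature_names = c("severity",
                      paste0("injury_", injuries),
                      "remaining_treatment_min", "wait_min",
                      "time_to_bound_min",
                      "seniority",
                      paste0("specialty_", injuries),
                      "status", "idle_min")
  ), class = "ed_schema")
}

#' Featurize a candidate patient-physician assignment
#'
#' @param patient list with `severity` (1-5), `injury`, `remaining_tt_min`
#'   (minutes of the current examination still to deliver), `wait_min`
#'   (minutes waited so far at this stage) and `tbar_min` (triage wait bound
#'   for this stage, minutes).
#' @param physician `NULL` for the wait-room dummy, else a list with
#'   `seniority` (one of assistant/intern/resident/attending), `specialty`
#'   (an injury type or `NA`), `status_severity` (0 if idle, else the severity
#'   of the patient currently under treatment) and `idle_min`.
#' @param schema an [ed_schema()].
#' @return Numeric feature vector of length `schema$length`.
#' @export
#' @examples
#' sch <- ed_schema(c("internal", "orthopedic"))
#' featurize_ed_pair(
#'   list(severity = 3, injury = "internal", remaining_tt_min = 20,
#'        wait_min = 10, tbar_min = 30),
#'   NULL, sch)
featurize_ed_pair <- function(patient, physician, schema) {
  stopifnot(inherits(schema, "ed_schema"))
  if (!(patient$injury %in% schema$injuries)) {
    stop_invalid("unknown injury type '", patient$injury, "' for schema ", schema$id)
  }
  inj <- as.numeric(schema$injuries == patient$injury)
  if (is.null(physician)) { # wait-room dummy
    sen <- 0
    spec <- numeric(length(schema$injuries))
    status <- 0
    idle <- 0
  } else {
    sen_idx <- match(physician$seniority, ED_SENIORITY)
    if (is.na(sen_idx)) stop_invalid("unknown seniority '", physician$seniority, "'")
    sen <- sen_idx / 4
    spec <- if (is.na(physician$specialty)) numeric(length(schema$injuries))
            else as.numeric(schema$injuries == physician$specialty)
    status <- physician$status_severity %||% 0
    idle <- physician$idle_min %||% 0
  }
  v <- c(patient$severity / 5, inj,
         patient$remaining_tt_min, patient$wait_min,
         patient$tbar_min - patient$wait_min,
         sen, spec, status, idle)
  names(v) <- schema$feature_names
  v
}
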