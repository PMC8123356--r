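# Exponential lateness loss and the binned lateness distribution.

#' Exponential lateness loss of one study
#'
#' \eqn{L(s) = \exp(2 \cdot \mathrm{lateness})} with lateness in hours
#' (signed: negative when the study is read before its deadline). The loss is
#' non-negative, additive across studies, and super-linear for non-negative
#' lateness, so one very tardy study costs more than several mildly tardy
#' ones.
#'
#' @param lateness_hours signed lateness in hours (vectorised).
#' @return Loss value(s).
#' @export
#' @examples
#' study_loss(0)   # 1
#' study_loss(-1)  # exp(-2)
study_loss <- function(lateness_hours) exp(2 * lateness_hours)

#' Total loss of a lateness report
#'
#' Additive over studies: the sum of per-study exponential losses.
#'
#' @param report a [lateness_report()] (or numeric lateness vector in hours).
#' @return Scalar total loss.
#' @export
total_loss <- function(report) {
  lat <- if (inherits(report, "lateness_report")) report$lateness_hours else report
  sum(study_loss(lat))
}

.LATENESS_BINS <- c("before_deadline", "slightly_over", "late",
                    "very_late", "extremely_late")

#' Bin lateness values into the five reporting categories
#'
#' Before the deadline; slightly over (less than 15 min after); late (15-45
#' min past); very late (45-60 min past); extremely late (more than 1 h
#' past). Fractions sum to 1.
#'
#' @param report a [lateness_report()] or numeric lateness vector in hours.
#' @return Named numeric vector of fractions over the five bins.
#' @export
#' @examples
#' bin_lateness(c(-5, 30, 70) / 60)
bin_lateness <- function(report) {
  lat <- if (inherits(report, "lateness_report")) report$lateness_hours else report
  mins <- lat * 60
  counts <- c(
    before_deadline = sum(mins <= 0),
    slightly_over = sum(mins > 0 & mins < 15),
    late = sum(mins >= 15 & mins < 45),
    very_late = sum(mins >= 45 & mins <= 60),
    extremely_late = sum(mins > 60)
  )
  if (!length(mins)) return(counts)
  counts / length(mins)
}

#' Per-study lateness report
#'
#' @param lateness_hours numeric vector of signed lateness values (hours).
#' @param ids optional study ids.
#' @return An object of class `lateness_report` with per-study lateness and
#'   loss, the total loss and the binned distribution.
#' @export
lateness_report <- function(lateness_hours, ids = seq_along(lateness_hours)) {
  structure(list(
    lateness_hours = lateness_hours,
    ids = ids,
    loss = study_loss(lateness_hours),
    total_loss = sum(study_loss(lateness_hours)),
    bins = bin_lateness(lateness_hours)
  ), class = "lateness_report")
}

#' @export
print.lateness_report <- function(x, ...) {
  cat("<lateness_report>", length(x$lateness_hours), "studies; total loss",
      signif(x$total_loss, 5), "\n")
  print(round(x$bins, 3))
  invisible(x)
}
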