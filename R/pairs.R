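# Decision events and preference pairs: the bridge between offline-optimal
# solutions and comparator training.

#' A single assignment decision event
#'
#' Records the feature vector of the option the (near-)optimal solution chose
#' at one decision instant, plus all non-chosen options available then.
#'
#' @param chosen numeric feature vector of the selected option.
#' @param rejected matrix with one non-chosen option per row (possibly zero
#'   rows), or a list of vectors.
#' @param event_id identifier of the decision instant.
#' @param schema_id feature schema identifier.
#' @return An object of class `decision_event`.
#' @export
decision_event <- function(chosen, rejected, event_id = "e", schema_id = "generic") {
  if (is.list(rejected)) {
    rejected <- if (length(rejected)) do.call(rbind, rejected) else
      matrix(numeric(0), 0, length(chosen))
  }
  stopifnot(is.numeric(chosen), is.matrix(rejected) || nrow(rejected) == 0)
  if (nrow(rejected) > 0 && ncol(rejected) != length(chosen)) {
    stop_invalid("chosen and rejected options must share one feature schema")
  }
  structure(list(chosen = as.numeric(chosen), rejected = rejected,
                 event_id = as.character(event_id), schema_id = schema_id),
            class = "decision_event")
}

#' Construct a preference-pair set
#'
#' @param preferred,rejected matrices with one feature vector per row;
#'   row `i` of `preferred` was chosen over row `i` of `rejected`.
#' @param schema_id feature schema identifier.
#' @param source_event character vector of originating event ids.
#' @return An object of class `preference_pairs`.
#' @export
preference_pairs <- function(preferred, rejected, schema_id = "generic",
                             source_event = rep("", nrow(preferred))) {
  stopifnot(is.matrix(preferred), is.matrix(rejected),
            nrow(preferred) == nrow(rejected),
            ncol(preferred) == ncol(rejected),
            length(source_event) == nrow(preferred))
  structure(list(preferred = preferred, rejected = rejected,
                 schema_id = schema_id,
                 source_event = as.character(source_event)),
            class = "preference_pairs")
}

#' @export
print.preference_pairs <- function(x, ...) {
  cat("<preference_pairs>", nrow(x$preferred), "pairs of dim",
      ncol(x$preferred), "schema:", x$schema_id, "\n")
  invisible(x)
}

#' Number of pairs in a preference-pair set
#' @param pairs a [preference_pairs()] object.
#' @return Integer count.
#' @export
n_pairs <- function(pairs) nrow(pairs$preferred)

#' Build comparator training pairs from decision events
#'
#' Every event with one chosen option and `n` non-chosen options contributes
#' exactly `n` pairs (chosen over each rejected). Events with no alternative
#' yield no pairs; events whose option set is empty are skipped with a warning.
#'
#' @param events list of [decision_event()] objects (nonempty).
#' @return A [preference_pairs()] object.
#' @export
#' @examples
#' ev <- decision_event(c(1, 0), rbind(c(0, 1), c(0, 0)), "e1")
#' n_pairs(build_training_pairs(list(ev))) # 2
build_training_pairs <- function(events) {
  if (!length(events)) stop_invalid("'events' must be a nonempty list")
  schema <- NULL
  pref <- list(); rej <- list(); src <- character(0)
  for (ev in events) {
    if (!inherits(ev, "decision_event")) stop_invalid("all events must be decision_event objects")
    if (is.null(ev$chosen) || !length(ev$chosen)) {
      warning("skipping decision event '", ev$event_id, "' with no options")
      next
    }
    schema <- schema %||% ev$schema_id
    if (!identical(schema, ev$schema_id)) {
      stop_invalid("events mix feature schemas ('", schema, "' vs '", ev$schema_id, "')")
    }
    k <- nrow(ev$rejected)
    if (k == 0L) next
    pref[[length(pref) + 1L]] <- matrix(ev$chosen, k, length(ev$chosen), byrow = TRUE)
    rej[[length(rej) + 1L]] <- ev$rejected
    src <- c(src, rep(ev$event_id, k))
  }
  d <- length(events[[1L]]$chosen)
  if (!length(pref)) {
    return(preference_pairs(matrix(numeric(0), 0, d), matrix(numeric(0), 0, d),
                            schema_id = schema %||% "generic",
                            source_event = character(0)))
  }
  preference_pairs(do.call(rbind, pref), do.call(rbind, rej),
                   schema_id = schema, source_event = src)
}

#' Write preference pairs to CSV
#'
#' One row per pair: `source_event`, `schema_id`, then the preferred vector
#' (columns `p1..pd`) and the rejected vector (`r1..rd`).
#'
#' @param pairs a [preference_pairs()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_preference_pairs <- function(pairs, path) {
  d <- ncol(pairs$preferred)
  df <- data.frame(source_event = pairs$source_event,
                   schema_id = pairs$schema_id)
  p <- as.data.frame(pairs$preferred)
  names(p) <- paste0("p", seq_len(d))
  r <- as.data.frame(pairs$rejected)
  names(r) <- paste0("r", seq_len(d))
  write.csv(cbind(df, p, r), path, row.names = FALSE)
  invisible(path)
}

#' Read preference pairs written by [write_preference_pairs()]
#' @param path file path.
#' @return A [preference_pairs()] object.
#' @export
read_preference_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pcols <- grep("^p[0-9]+$", names(df))
  rcols <- grep("^r[0-9]+$", names(df))
  preference_pairs(as.matrix(df[, pcols, drop = FALSE]),
                   as.matrix(df[, rcols, drop = FALSE]),
                   schema_id = df$schema_id[1] %||% "generic",
                   source_event = df$source_event)
}
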