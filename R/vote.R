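# Using the comparator online: all-pairs majority vote and ordered insertion.

#' Select a candidate by all-pairs majority vote
#'
#' Every unordered pair of candidates is compared once; each comparison awards
#' one point to the winner (score above 0.5). An exact 0.5 awards half a point
#' to each side, so the tournament is independent of candidate order. The
#' candidate with the most points wins; ties are broken uniformly at random
#' from R's current RNG stream.
#'
#' @param model a [comparator()].
#' @param candidates matrix with one feature vector per row (nonempty).
#' @return The index (row number) of the selected candidate.
#' @export
majority_vote_select <- function(model, candidates) {
  stopifnot(inherits(model, "comparator"), is.matrix(candidates))
  n <- nrow(candidates)
  if (n == 0L) stop_invalid("candidate list is empty")
  if (n == 1L) return(1L)
  pts <- tournament_points(model, candidates)
  top <- which(pts >= max(pts) - 1e-12)
  if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
}

#' All-pairs tournament points
#'
#' @param model a [comparator()].
#' @param candidates matrix with one feature vector per row.
#' @return Numeric vector of points per candidate (1 per comparison won, 0.5
#'   each for an exact draw).
#' @export
tournament_points <- function(model, candidates) {
  n <- nrow(candidates)
  pts <- numeric(n)
  if (n < 2L) return(pts)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s <- compare_many(model, candidates[ij[, 1L], , drop = FALSE],
                    candidates[ij[, 2L], , drop = FALSE])
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1L]; j <- ij[r, 2L]
    if (abs(s[r] - 0.5) <= .Machine$double.eps) {
      pts[i] <- pts[i] + 0.5
      pts[j] <- pts[j] + 0.5
    } else if (s[r] > 0.5) {
      pts[i] <- pts[i] + 1
    } else {
      pts[j] <- pts[j] + 1
    }
  }
  pts
}

#' Insert an item into an ordered pool using the comparator
#'
#' Scans the pool from the highest rank and places the new item at the first
#' position whose incumbent it is (weakly) preferred over (score >= 0.5);
#' otherwise appends it last. The relative order of incumbents is unchanged.
#'
#' @param model a [comparator()].
#' @param ordered_pool matrix with one feature vector per row, ranked best
#'   first (possibly zero rows).
#' @param new_item numeric feature vector.
#' @return List with `pool` (the new matrix) and `position` (1-based rank of
#'   the inserted item).
#' @export
insert_by_partial_order <- function(model, ordered_pool, new_item) {
  stopifnot(inherits(model, "comparator"))
  if (is.null(ordered_pool)) ordered_pool <- matrix(numeric(0), 0, length(new_item))
  n <- nrow(ordered_pool)
  if (n == 0L) {
    return(list(pool = matrix(new_item, 1L), position = 1L))
  }
  s <- compare_many(model,
                    matrix(new_item, n, length(new_item), byrow = TRUE),
                    ordered_pool)
  pos <- which(s >= 0.5)
  pos <- if (length(pos)) pos[1L] else n + 1L
  pool <- rbind(
    ordered_pool[seq_len(pos - 1L), , drop = FALSE],
    matrix(new_item, 1L),
    if (pos <= n) ordered_pool[pos:n, , drop = FALSE]
  )
  list(pool = pool, position = pos)
}
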