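# Internal helpers: seed streams, argument checks, small numerics.

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Named streams
#' (scenario generation, training, simulation, tie-breaking, ...) get their own
#' deterministic sub-seeds so that stages can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @param index integer index within the stream (e.g. scenario number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "scenario", 1)
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m)
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# clamp helper
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
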