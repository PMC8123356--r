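# Anti-symmetric pairwise comparator network.
#
# Two weight-shared towers are cross-wired: at every layer the weight matrix
# from the first input to the first hidden vector equals the matrix from the
# second input to the second hidden vector (W11), and the two cross connections
# share W12; the bias is shared. The output is sigmoid(w . (H1 - H2)) where
# H1, H2 are the two top hidden vectors. Swapping the inputs therefore swaps
# H1 and H2 and negates the logit, so C(x, y) + C(y, x) = 1 and C(x, x) = 0.5
# hold by construction for any weights, trained or not.

#' Create an untrained anti-symmetric comparator
#'
#' Builds the cross-wired shared-weight pairwise comparator \eqn{C(x,y) \in
#' [0,1]}. Reflexivity (\eqn{C(x,x)=0.5}) and anti-symmetry
#' (\eqn{C(x,y)+C(y,x)=1}) are structural properties of the architecture and
#' hold for arbitrary (e.g. random) weights.
#'
#' @param input_dim length of each input feature vector.
#' @param hidden integer vector of hidden-layer widths (default two layers of
#'   32 units, tanh activations).
#' @param schema_id identifier of the feature schema the comparator accepts;
#'   `compare()` refuses vectors from a different schema.
#' @param seed integer seed for the weight initialisation.
#' @param center,scale optional per-feature standardisation applied to both
#'   inputs before the towers (the same affine map on both sides preserves
#'   reflexivity and anti-symmetry). Defaults: no standardisation.
#' @return An object of class `comparator`.
#' @seealso [compare()], [train_comparator()], [majority_vote_select()]
#' @export
comparator <- function(input_dim, hidden = c(32L, 32L), schema_id = "generic",
                       seed = 1L, center = NULL, scale = NULL) {
  stopifnot(is_scalar_num(input_dim), input_dim >= 1, length(hidden) >= 1)
  input_dim <- as.integer(input_dim)
  hidden <- as.integer(hidden)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  dims <- c(input_dim, hidden)
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    fan_in <- 2L * dims[l] # each unit sees both towers
    fan_out <- dims[l + 1L]
    r <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W11 = matrix(runif(fan_out * dims[l], -r, r), fan_out, dims[l]),
      W12 = matrix(runif(fan_out * dims[l], -r, r), fan_out, dims[l]),
      b = numeric(fan_out)
    )
  }
  w_out <- runif(hidden[length(hidden)], -0.5, 0.5)
  structure(list(
    input_dim = input_dim, hidden = hidden, schema_id = schema_id,
    layers = layers, w_out = w_out,
    center = center %||% numeric(input_dim),
    scale = scale %||% rep(1, input_dim),
    seed = as.integer(seed), loss_history = numeric(0)
  ), class = "comparator")
}

# Save/restore global RNG state so constructors don't perturb caller streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Forward pass on column matrices X, Y (input_dim x n). Returns list with the
# per-layer activations (needed by backprop) and the preference scores.
.comparator_forward <- function(model, X, Y) {
  if (!is.null(model$clip_lo)) {
    # clamp to the training range: outside it the network would extrapolate
    # through saturated units; the identical clamp on both towers preserves
    # reflexivity and anti-symmetry
    X <- pmin(pmax(X, model$clip_lo), model$clip_hi)
    Y <- pmin(pmax(Y, model$clip_lo), model$clip_hi)
  }
  X <- (X - model$center) / model$scale
  Y <- (Y - model$center) / model$scale
  A1 <- list(X)
  A2 <- list(Y)
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    A1[[l + 1L]] <- tanh(ly$W11 %*% A1[[l]] + ly$W12 %*% A2[[l]] + ly$b)
    A2[[l + 1L]] <- tanh(ly$W11 %*% A2[[l]] + ly$W12 %*% A1[[l]] + ly$b)
  }
  K <- length(A1)
  z <- as.numeric(crossprod(model$w_out, A1[[K]] - A2[[K]]))
  list(A1 = A1, A2 = A2, z = z, score = plogis(z))
}

.check_schema <- function(model, v, arg = "x") {
  if (!is.numeric(v) || length(v) != model$input_dim || any(!is.finite(v))) {
    stop_invalid("comparator input '", arg, "' must be a finite numeric vector of length ",
                 model$input_dim, " (schema '", model$schema_id, "')")
  }
}

#' Compare two feature vectors
#'
#' Returns the preference score \eqn{C(x,y) \in [0,1]}: values above 0.5 mean
#' the comparator prefers `x` over `y`.
#'
#' @param model a [comparator()].
#' @param x,y numeric feature vectors of the model's schema.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' m <- comparator(3, hidden = c(8, 8), seed = 42)
#' compare(m, c(1, 0, 0), c(1, 0, 0)) # exactly 0.5
compare <- function(model, x, y) {
  stopifnot(inherits(model, "comparator"))
  .check_schema(model, x, "x")
  .check_schema(model, y, "y")
  .comparator_forward(model, matrix(x), matrix(y))$score
}

#' Vectorised comparison of many pairs
#'
#' @param model a [comparator()].
#' @param X,Y matrices with one feature vector per row.
#' @return Numeric vector of scores, one per row pair.
#' @export
compare_many <- function(model, X, Y) {
  stopifnot(inherits(model, "comparator"),
            is.matrix(X), is.matrix(Y),
            ncol(X) == model$input_dim, ncol(Y) == model$input_dim,
            nrow(X) == nrow(Y))
  .comparator_forward(model, t(X), t(Y))$score
}

# Gradient of mean binary cross-entropy (target 1 for (preferred, rejected))
# over a batch. Returns list(grads, loss). Shapes mirror model$layers/$w_out.
.comparator_grad <- function(model, X, Y) {
  fw <- .comparator_forward(model, X, Y)
  n <- ncol(X)
  s <- fw$score
  loss <- -mean(log(pmax(s, 1e-12)))
  dz <- (s - 1) / n # d loss / d z, length n
  K <- length(fw$A1)
  dw_out <- as.numeric((fw$A1[[K]] - fw$A2[[K]]) %*% dz)
  D1 <- model$w_out %o% dz
  D2 <- -D1
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    G1 <- D1 * (1 - fw$A1[[l + 1L]]^2)
    G2 <- D2 * (1 - fw$A2[[l + 1L]]^2)
    grads[[l]] <- list(
      W11 = tcrossprod(G1, fw$A1[[l]]) + tcrossprod(G2, fw$A2[[l]]),
      W12 = tcrossprod(G1, fw$A2[[l]]) + tcrossprod(G2, fw$A1[[l]]),
      b = rowSums(G1) + rowSums(G2)
    )
    if (l > 1L) {
      D1p <- crossprod(ly$W11, G1) + crossprod(ly$W12, G2)
      D2p <- crossprod(ly$W12, G1) + crossprod(ly$W11, G2)
      D1 <- D1p
      D2 <- D2p
    }
  }
  list(grads = grads, dw_out = dw_out, loss = loss)
}

#' Train a comparator on preference pairs
#'
#' Fits the cross-wired shared-weight comparator by minimising binary
#' cross-entropy with target \eqn{C(\mathrm{preferred}, \mathrm{rejected}) = 1}
#' (the RankNet-style probabilistic reading of a pairwise preference), using
#' mini-batch Adam. Inputs are standardised per feature using statistics of the
#' training pairs; the identical affine map is applied to both towers so the
#' structural reflexivity/anti-symmetry guarantees are unaffected. Training is
#' fully reproducible from `seed` (initialisation and batch shuffling).
#'
#' @param pairs a [preference_pairs()] object with at least one pair.
#' @param hidden hidden-layer widths (default `c(32, 32)`).
#' @param lr Adam learning rate (default `1e-3`).
#' @param epochs number of passes over the pairs (default 200).
#' @param batch_size mini-batch size (default 64).
#' @param seed integer seed.
#' @param standardize standardise features from the training pairs (default
#'   TRUE).
#' @return A trained `comparator`; `$loss_history` holds the mean epoch loss.
#' @export
train_comparator <- function(pairs, hidden = c(32L, 32L), lr = 1e-3,
                             epochs = 200L, batch_size = 64L, seed = 1L,
                             standardize = TRUE) {
  stopifnot(inherits(pairs, "preference_pairs"))
  n <- nrow(pairs$preferred)
  if (n < 1L) stop_invalid("cannot train a comparator on an empty pair list")
  d <- ncol(pairs$preferred)
  center <- numeric(d)
  scl <- rep(1, d)
  clip_lo <- clip_hi <- NULL
  if (standardize) {
    all_rows <- rbind(pairs$preferred, pairs$rejected)
    center <- colMeans(all_rows)
    scl <- apply(all_rows, 2, sd)
    scl[!is.finite(scl) | scl < 1e-9] <- 1
    clip_lo <- apply(all_rows, 2, min)
    clip_hi <- apply(all_rows, 2, max)
  }
  model <- comparator(d, hidden = hidden, schema_id = pairs$schema_id,
                      seed = seed, center = center, scale = scl)
  model$clip_lo <- clip_lo
  model$clip_hi <- clip_hi
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  params <- c(unlist(lapply(seq_along(model$layers), function(l) {
    stats::setNames(model$layers[[l]], paste0(c("W11", "W12", "b"), ".", l))
  }), recursive = FALSE), list(w_out = model$w_out))
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  Xall <- t(pairs$preferred) # d x n
  Yall <- t(pairs$rejected)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      g <- .comparator_grad(model, Xall[, idx, drop = FALSE],
                            Yall[, idx, drop = FALSE])
      if (!is.finite(g$loss)) {
        stop_invalid("comparator training diverged (non-finite loss at epoch ",
                     ep, ")")
      }
      ep_loss <- ep_loss + g$loss
      nb <- nb + 1L
      gl <- c(unlist(lapply(seq_along(g$grads), function(l) {
        stats::setNames(g$grads[[l]], paste0(c("W11", "W12", "b"), ".", l))
      }), recursive = FALSE), list(w_out = g$dw_out))
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gl[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gl[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      # write back into the model used by forward/grad
      for (l in seq_along(model$layers)) {
        model$layers[[l]]$W11 <- params[[paste0("W11.", l)]]
        model$layers[[l]]$W12 <- params[[paste0("W12.", l)]]
        model$layers[[l]]$b <- params[[paste0("b.", l)]]
      }
      model$w_out <- params$w_out
    }
    history[ep] <- ep_loss / nb
  }
  model$loss_history <- history
  model$trained_on <- n
  model
}

#' @export
print.comparator <- function(x, ...) {
  cat("<comparator> schema:", x$schema_id,
      " input_dim:", x$input_dim,
      " hidden:", paste(x$hidden, collapse = "-"), "\n")
  if (length(x$loss_history)) {
    cat("  trained on", x$trained_on, "pairs;",
        length(x$loss_history), "epochs; final loss",
        signif(x$loss_history[length(x$loss_history)], 4), "\n")
  } else {
    cat("  untrained (random weights; anti-symmetry still holds)\n")
  }
  invisible(x)
}

#' Serialise a comparator to a portable JSON archive
#'
#' @param model a [comparator()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_comparator <- function(model, path) {
  stopifnot(inherits(model, "comparator"))
  obj <- list(
    format = "lbassign-comparator-v1",
    schema_id = model$schema_id,
    input_dim = model$input_dim,
    hidden = model$hidden,
    seed = model$seed,
    center = model$center,
    scale = model$scale,
    clip_lo = model$clip_lo,
    clip_hi = model$clip_hi,
    w_out = model$w_out,
    layers = lapply(model$layers, function(ly) {
      list(W11 = ly$W11, W12 = ly$W12, b = ly$b)
    }),
    loss_history = model$loss_history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a comparator written by [write_comparator()]
#'
#' @param path file path.
#' @return A `comparator`.
#' @export
read_comparator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "lbassign-comparator-v1")) {
    stop_invalid("not a comparator archive: ", path)
  }
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r)))
  hidden <- as.integer(unlist(obj$hidden))
  structure(list(
    input_dim = as.integer(obj$input_dim),
    hidden = hidden,
    schema_id = obj$schema_id,
    layers = lapply(obj$layers, function(ly) {
      list(W11 = as_mat(ly$W11), W12 = as_mat(ly$W12),
           b = as.numeric(unlist(ly$b)))
    }),
    w_out = as.numeric(unlist(obj$w_out)),
    center = as.numeric(unlist(obj$center)),
    scale = as.numeric(unlist(obj$scale)),
    clip_lo = if (!is.null(obj$clip_lo)) as.numeric(unlist(obj$clip_lo)),
    clip_hi = if (!is.null(obj$clip_hi)) as.numeric(unlist(obj$clip_hi)),
    seed = as.integer(obj$seed),
    loss_history = as.numeric(unlist(obj$loss_history))
  ), class = "comparator")
}
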