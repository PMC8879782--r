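#' PCA motion model from a set of displacement fields
#'
#' Flattens each DVF to one sample vector, subtracts the sample mean, and
#' computes the principal modes of the centred sample matrix (via the
#' eigen-decomposition of its Gram matrix, equivalent to the SVD). The
#' model represents any breathing state as
#' `D(u) = D_mean + sum_i u_i v_i`, with unit-norm, mutually orthogonal
#' eigenvector fields `v_i` sorted by descending eigenvalue and per-phase
#' training scores `u_i(t)`. Each eigenvector's sign is fixed so that its
#' largest-magnitude SI component is positive.
#'
#' @param dvfs list of [dvf()] on a common grid (>= 2); by convention the
#'   reference phase's zero field is included as a training sample.
#' @param n_modes number of retained modes N (default 3); truncated with a
#'   warning when it exceeds `length(dvfs) - 1`.
#' @return an object of class `pca_motion_model` with elements `mean`
#'   (flattened mean DVF), `modes` (features x N matrix), `eigenvalues`
#'   (all non-negative eigenvalues, descending, variance units),
#'   `scores` (samples x N training coefficients), `n_modes`, and the grid
#'   description (`dim`, `spacing`, `origin`).
#' @export
build_pca_model <- function(dvfs, n_modes = 3) {
  if (length(dvfs) < 2) stop("need at least 2 DVFs to build a motion model")
  for (d in dvfs[-1]) check_same_grid(dvfs[[1]], d)
  n <- length(dvfs)
  X <- t(vapply(dvfs, function(d) as.vector(d$field),
                numeric(length(dvfs[[1]]$field))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  G <- tcrossprod(Xc)                      # n x n Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  ssq <- pmax(eg$values, 0)                # squared singular values
  pos <- ssq > max(ssq, 1e-300) * 1e-12
  rank <- sum(pos)
  if (n_modes > n - 1) {
    warning(sprintf("n_modes = %d exceeds samples - 1 = %d; truncating",
                    n_modes, n - 1))
    n_modes <- n - 1
  }
  nm <- min(n_modes, max(rank, 1))
  modes <- matrix(0, ncol(X), nm)
  scores <- matrix(0, n, nm)
  for (i in seq_len(nm)) {
    if (pos[i]) {
      sv <- sqrt(ssq[i])
      modes[, i] <- crossprod(Xc, eg$vectors[, i]) / sv
      scores[, i] <- eg$vectors[, i] * sv
    }
  }
  # sign convention: dominant SI component positive
  nvox <- ncol(X) / 3
  si <- (2 * nvox + 1):(3 * nvox)
  for (i in seq_len(nm)) {
    blk <- modes[si, i]
    j <- which.max(abs(blk))
    ref <- if (abs(blk[j]) > 1e-12) blk[j] else
      modes[which.max(abs(modes[, i])), i]
    if (isTRUE(ref < 0)) {
      modes[, i] <- -modes[, i]
      scores[, i] <- -scores[, i]
    }
  }
  structure(list(mean = mu, modes = modes,
                 eigenvalues = ssq / (n - 1),
                 scores = scores, n_modes = nm,
                 dim = dim(dvfs[[1]]$field)[1:3],
                 spacing = dvfs[[1]]$spacing,
                 origin = dvfs[[1]]$origin),
            class = "pca_motion_model")
}

#' @export
print.pca_motion_model <- function(x, ...) {
  ev <- explained_variance(x)
  cat(sprintf("pca_motion_model: %d modes on a %d x %d x %d grid\n",
              x$n_modes, x$dim[1], x$dim[2], x$dim[3]))
  cat(sprintf("  cumulative explained variance (retained modes): %.1f%%\n",
              100 * ev$cumulative[x$n_modes]))
  invisible(x)
}

#' Displacement field for a coefficient vector
#'
#' Evaluates `D(u) = D_mean + sum_i u_i v_i` and reshapes it onto the model
#' grid. Linear in `u`; `u = 0` returns the mean field exactly.
#'
#' @param model a [build_pca_model()] result.
#' @param u coefficient vector of length `model$n_modes`.
#' @return a [dvf()].
#' @export
reconstruct_dvf <- function(model, u) {
  if (length(u) != model$n_modes)
    stop(sprintf("coefficient vector must have length %d", model$n_modes))
  v <- model$mean + as.vector(model$modes %*% as.numeric(u))
  dvf(array(v, c(model$dim, 3L)), model$spacing, model$origin,
      provenance = "pca_motion_model::reconstruct_dvf")
}

#' Per-mode and cumulative explained variance
#'
#' `ratio_i = lambda_i / sum_j lambda_j` over the full eigenvalue spectrum;
#' ratios sum to 1 over all non-zero modes.
#'
#' @param model a `pca_motion_model`.
#' @return list with `ratio`, `cumulative` and `eigenvalues`.
#' @export
explained_variance <- function(model) {
  ev <- model$eigenvalues
  tot <- sum(ev)
  if (tot <= 0) stop("undefined explained-variance ratio: all eigenvalues are zero")
  list(ratio = ev / tot, cumulative = cumsum(ev) / tot, eigenvalues = ev)
}
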