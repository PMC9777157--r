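# MinMax scaling and covariance PCA for the deep-feature head. Both are fit
# on the training partition only; applying them to test rows may produce
# values outside [0,1] / the training subspace, which is expected.

#' Fit a MinMax scaler on training features
#'
#' Column-wise `(x - min) / (max - min)`. Constant columns (max == min) are
#' mapped to 0 to avoid division by zero.
#'
#' @param x numeric matrix, one row per training sample.
#' @return a `minmax_scaler` with per-feature `min` and `max`.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop_kneedhl("need at least one row", "kneedhl_invalid_input")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`.
#' @export
minmax_transform <- function(x, scaler) {
  x <- as.matrix(x)
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- Inf  # constant feature -> 0
  sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
}

#' Fit PCA on (scaled) training features at a variance target
#'
#' Eigendecomposes the sample covariance matrix of the input; keeps the
#' minimal number of leading components whose cumulative explained-variance
#' ratio reaches `variance_target` (default 99 percent).
#'
#' @param x numeric matrix (training rows x features).
#' @param variance_target fraction of variance to preserve, in (0, 1\].
#' @return a `pca_model` with the covariance matrix, eigenvalues (descending),
#'   orthonormal `components` (columns), `explained_variance_ratio`,
#'   `n_components` and the feature means used for centring.
#' @export
fit_pca <- function(x, variance_target = 0.99) {
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
    stop_kneedhl("variance_target must lie in (0, 1]", "kneedhl_config_error")
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_kneedhl("PCA needs at least 2 samples", "kneedhl_invalid_input")
  centre <- colMeans(x)
  A <- cov(x)
  eig <- eigen(A, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  total <- sum(values)
  evr <- if (total > 0) values / total else rep(0, length(values))
  ncomp <- if (total > 0) {
    which(cumsum(evr) >= variance_target - 1e-12)[1]
  } else {
    1L
  }
  structure(list(covariance = A, eigenvalues = values,
                 components = eig$vectors[, seq_len(ncomp), drop = FALSE],
                 explained_variance_ratio = evr, n_components = as.integer(ncomp),
                 variance_target = variance_target, center = centre),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param pca a fitted `pca_model`.
#' @export
pca_reduce <- function(x, pca) {
  x <- as.matrix(x)
  stopifnot(inherits(pca, "pca_model"), ncol(x) == length(pca$center))
  sweep(x, 2, pca$center, "-") %*% pca$components
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d/%d components, %.2f%% variance (target %.0f%%)\n",
              x$n_components, length(x$eigenvalues),
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)]),
              100 * x$variance_target))
  invisible(x)
}
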