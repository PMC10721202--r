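#' PCA feature reduction of per-layer activations
#'
#' A convolution layer can carry millions of activations per image, far
#' too many for a regression model. Each layer's images x activations
#' matrix is therefore reduced by a column-centered PCA, keeping the
#' smallest leading set of components whose cumulative explained
#' variance reaches a target fraction (default 0.80). PC signs are
#' fixed by forcing the largest-magnitude loading of each component to
#' be positive, so results are reproducible across platforms.
#'
#' @param activations numeric matrix, `n_images x d` (n >= 3, d >= 1).
#' @param variance_target fraction of variance to retain, in `(0, 1]`.
#' @param layer_id optional layer label stored with the result.
#' @return a `feature_matrix`: list with `layer_id`, `scores`
#'   (`n_images x k` PC scores), `explained_fraction` (all components,
#'   non-increasing, summing to 1), `k` (retained count), `rotation`
#'   (`d x k` loadings), `center`, `variance_target`.
#' @export
pca_retain <- function(activations, variance_target = 0.80,
                       layer_id = NULL) {
  stopifnot(is.matrix(activations))
  n <- nrow(activations)
  d <- ncol(activations)
  if (n < 3L) stop("PCA needs at least 3 images", call. = FALSE)
  if (!is.numeric(variance_target) || variance_target <= 0 ||
      variance_target > 1) {
    stop("variance_target must lie in (0, 1]", call. = FALSE)
  }
  total_var <- sum(apply(activations, 2L, stats::var))
  if (total_var <= 0) {
    stop("degenerate input: activation matrix has zero variance",
         call. = FALSE)
  }
  p <- stats::prcomp(activations, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  # floating-point boundary tolerance: a cumulative fraction that equals
  # the target analytically must count as reaching it
  k <- which(cumsum(frac) >= variance_target - 1e-8)[1L]
  scores <- p$x[, seq_len(k), drop = FALSE]
  rotation <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(rotation[, j]))
    if (rotation[lead, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(layer_id = layer_id, scores = scores,
         explained_fraction = frac, k = k, rotation = rotation,
         center = p$center, variance_target = variance_target),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", x$layer_id %||% "", "-", nrow(x$scores),
      "images,", x$k, "components retained (",
      sprintf("%.1f%%", 100 * sum(x$explained_fraction[seq_len(x$k)])),
      "of variance, target",
      sprintf("%.0f%%", 100 * x$variance_target), ")\n")
  invisible(x)
}

#' Leading-k principal-component scores
#'
#' @param fm a `feature_matrix` from [pca_retain()].
#' @param k number of leading components, `0 <= k <= fm$k`.
#' @return `n_images x k` score matrix (eigenvalue order).
#' @export
first_k_scores <- function(fm, k) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (k > fm$k) {
    stop("requested ", k, " components but only ", fm$k, " were retained",
         call. = FALSE)
  }
  fm$scores[, seq_len(k), drop = FALSE]
}

#' Z-score the columns of a predictor matrix
#'
#' Centers and scales every column to mean 0 and sample standard
#' deviation 1 (n-1 denominator).
#'
#' @param X numeric matrix; every column must have positive variance.
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(X)[sds == 0 | !is.finite(sds)] %||%
      which(sds == 0 | !is.finite(sds))
    stop("degenerate input: constant column(s) cannot be z-scored: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- scale(X, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}
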