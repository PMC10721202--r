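#' Sparsity metrics for neural activation vectors
#'
#' Sparsity here means inequity of the activation distribution of one
#' network layer for one image: a sparse code concentrates activity in a
#' few strongly active units while most units stay near zero. The Gini
#' index is the primary metric (0 for a perfectly uniform code, (n-1)/n
#' for a one-hot code); the Treves-Rolls sparseness is provided as the
#' common neuroscience alternative.
#'
#' @name sparsity-metrics
NULL

# Shared input contract for all sparsity metrics: post-ReLU activation
# vectors are finite, non-negative, of length >= 2, and not all zero
# (a layer that never fires has no defined code inequity).
check_activation_vector <- function(x) {
  if (!is.numeric(x)) {
    stop("activation vector must be numeric", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("sparsity is undefined for vectors of length < 2", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("activation vector contains non-finite values", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("activation vector contains negative values; sparsity metrics ",
         "require post-ReLU (non-negative) activations", call. = FALSE)
  }
  if (all(x == 0)) {
    stop("all-zero activation vector: sparsity is undefined", call. = FALSE)
  }
  invisible(x)
}

#' Gini index of an activation vector
#'
#' Computes \eqn{G = \sum_i (2i - n - 1) x_i / (n \sum_i x_i)} with the
#' activations sorted in ascending order and `i` 1-based. `G` lies in
#' `[0, (n-1)/n]`: 0 for a constant (perfectly equal) code, the maximum
#' for a one-hot code. Sums accumulate in extended precision, so vectors
#' of several million entries (a full early convolution layer) are safe.
#'
#' @param x numeric vector of non-negative activations, length >= 2,
#'   at least one entry positive.
#' @return a single number in `[0, (n-1)/n]`.
#' @examples
#' gini_index(c(1, 1, 1, 1))  # 0: uniform code
#' gini_index(c(0, 0, 0, 1))  # 0.75: one-hot code, n = 4
#' @seealso [gini_pairwise_oracle()] for an independent cross-check,
#'   [treves_rolls_sparseness()].
#' @export
gini_index <- function(x) {
  check_activation_vector(x)
  n <- length(x)
  xs <- sort(x, method = "radix")
  i <- seq_len(n)
  sum((2 * i - n - 1) * xs) / (n * sum(xs))
}

#' Pairwise-difference Gini oracle
#'
#' Brute-force Gini index as the normalized mean absolute pairwise
#' difference, \eqn{\sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}, computed
#' by an explicit double loop with no sorting. Mathematically identical
#' to [gini_index()]; kept as an independent verification path (the two
#' share no code), so it is quadratic and only meant for short vectors.
#'
#' @inheritParams gini_index
#' @return a single number in `[0, (n-1)/n]`.
#' @export
gini_pairwise_oracle <- function(x) {
  check_activation_vector(x)
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + abs(x[i] - x[j])
    }
  }
  acc / (2 * n^2 * mean(x))
}

#' Treves-Rolls sparseness
#'
#' Population sparseness `S = 1 - a` with
#' \eqn{a = (\sum x_i / n)^2 / (\sum x_i^2 / n)}, the classic
#' neuroscience measure. `S` lies in `[0, 1 - 1/n]`: 0 for a constant
#' code, the maximum for a one-hot code. No small-n normalization of
#' `1 - a` is applied; the metric name travels with every output table
#' so the convention is auditable.
#'
#' @inheritParams gini_index
#' @return a single number in `[0, 1 - 1/n]`.
#' @export
treves_rolls_sparseness <- function(x) {
  check_activation_vector(x)
  a <- mean(x)^2 / mean(x^2)
  1 - a
}

#' Sparsity profile of a set of encoded images
#'
#' Applies one sparsity metric to every per-layer activation vector of
#' every image, producing the images x layers matrix that downstream
#' regression models consume.
#'
#' @param activations list over images; each element a named list of
#'   numeric activation vectors, one per layer (all images must share
#'   the same layer names, e.g. the output of
#'   [extract_layer_activations()] or [generate_activations()]).
#' @param metric `"gini"` (default) or `"treves_rolls"`.
#' @return numeric matrix `n_images x n_layers` with layer ids as column
#'   names, image ids as row names, and the metric recorded in
#'   `attr(, "metric")`.
#' @export
sparsity_profile <- function(activations, metric = c("gini", "treves_rolls")) {
  metric <- match.arg(metric)
  stopifnot(is.list(activations), length(activations) >= 1L)
  layer_ids <- names(activations[[1L]])
  if (is.null(layer_ids)) {
    stop("per-image activations must be a named list of layers", call. = FALSE)
  }
  fun <- switch(metric, gini = gini_index, treves_rolls = treves_rolls_sparseness)
  vals <- vapply(activations, function(img) {
    if (!identical(names(img), layer_ids)) {
      stop("all images must share the same layer set", call. = FALSE)
    }
    vapply(img, fun, numeric(1))
  }, numeric(length(layer_ids)))
  prof <- if (length(layer_ids) == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(prof) <- list(
    names(activations) %||% paste0("img_", seq_len(nrow(prof))),
    layer_ids
  )
  attr(prof, "metric") <- metric
  prof
}
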