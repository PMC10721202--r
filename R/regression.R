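#' Repeated cross-validated regression battery
#'
#' The quantitative heart of the pipeline: beauty scores are regressed
#' on layer-wise sparsity and on PCA-reduced activation features with
#' five model families, evaluated by k-fold cross-validation repeated
#' many times. Held-out R-squared is computed per test fold as
#' `1 - SSE/SST` with SST centered on the test-fold mean, averaged over
#' folds and then over repeats; negative values are retained (a model
#' can predict worse than the test-fold mean). Ridge penalty strength
#' is chosen from a lambda grid by nested inner cross-validation on
#' each training fold. Significance comes from a seeded permutation
#' test of the response.
#'
#' @name regression-suite
NULL

#' Cross-validation configuration
#'
#' @param folds number of CV folds (>= 2).
#' @param repeats number of CV repetitions (>= 1).
#' @param seed integer seed governing fold assignment, inner-CV splits
#'   and permutations.
#' @param lambda_grid positive ridge penalties to search; default 50
#'   log-spaced values in `[1e-4, 1e4]` (on z-scored predictors).
#' @param permutations permutation count for p-values.
#' @return a `cv_config` list.
#' @export
cv_config <- function(folds = 10L, repeats = 100L, seed = 1L,
                      lambda_grid = 10^seq(-4, 4, length.out = 50),
                      permutations = 10000L) {
  stopifnot(folds >= 2L, repeats >= 1L,
            length(lambda_grid) >= 1L, all(lambda_grid > 0))
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), lambda_grid = as.numeric(lambda_grid),
                 permutations = as.integer(permutations)),
            class = "cv_config")
}

#' Deterministic fold assignment
#'
#' Partitions `1:n` into `cfg$folds` near-equal test folds. The
#' assignment is fully determined by `(cfg$seed, repeat_index)`.
#'
#' @param n number of observations (>= `cfg$folds`).
#' @param cfg a [cv_config()].
#' @param repeat_index which CV repetition the folds belong to.
#' @return integer vector of fold labels in `1:folds`, length `n`.
#' @export
make_folds <- function(n, cfg, repeat_index = 1L) {
  stopifnot(inherits(cfg, "cv_config"))
  if (n < cfg$folds) {
    stop("need at least as many observations (", n, ") as folds (",
         cfg$folds, ")", call. = FALSE)
  }
  with_seed(derive_seed(cfg$seed, repeat_index),
            sample(rep_len(seq_len(cfg$folds), n)))
}

# Held-out R-squared: SST centered on the test-fold mean; not clipped.
cv_r2 <- function(y_true, y_pred) {
  1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
}

adjusted_r2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

new_regression_result <- function(model_family, r2, r2_adjusted,
                                  coefficients, per_fold_scores,
                                  n_predictors, n, lambda = NA_real_,
                                  p_value = NA_real_) {
  structure(
    list(model_family = model_family, r2 = r2, r2_adjusted = r2_adjusted,
         coefficients = coefficients, p_value = p_value,
         per_fold_scores = per_fold_scores, n_predictors = n_predictors,
         n = n, lambda = lambda),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s: CV R2 = %.4f (adj %.4f), p = %s, %d predictor(s), n = %d\n",
              x$model_family, x$r2,
              x$r2_adjusted %||% NA_real_,
              ifelse(is.na(x$p_value), "NA", format(x$p_value)),
              x$n_predictors, x$n))
  invisible(x)
}

#' Cross-validated univariate linear regression
#'
#' Ordinary least squares of `y` on a single (z-scored) predictor,
#' fitted on each training fold and scored on the held-out fold.
#' The reported coefficient comes from the full-data fit.
#'
#' @param x numeric predictor vector (typically z-scored sparsity of
#'   one layer).
#' @param y numeric response (beauty scores).
#' @param cfg a [cv_config()].
#' @param model_family label stored in the result.
#' @return a `regression_result`.
#' @export
fit_univariate <- function(x, y, cfg, model_family = "sparsity_per_layer") {
  stopifnot(inherits(cfg, "cv_config"), length(x) == length(y))
  n <- length(y)
  if (stats::sd(x) == 0) {
    stop("degenerate input: predictor has zero variance", call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow = cfg$folds, ncol = cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    fold <- make_folds(n, cfg, r)
    for (f in seq_len(cfg$folds)) {
      te <- fold == f
      cf <- ols_1d(x[!te], y[!te])
      scores[f, r] <- cv_r2(y[te], cf[1L] + cf[2L] * x[te])
    }
  }
  r2 <- mean(colMeans(scores))
  cf_full <- ols_1d(x, y)
  new_regression_result(
    model_family, r2 = r2, r2_adjusted = adjusted_r2(r2, n, 1L),
    coefficients = c(intercept = cf_full[1L], slope = cf_full[2L]),
    per_fold_scores = scores, n_predictors = 1L, n = n
  )
}

ols_1d <- function(x, y) {
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  c(mean(y) - slope * mean(x), slope)
}

ridge_path <- function(X, y, lambda_grid) {
  glmnet::glmnet(X, y, alpha = 0,
                 lambda = sort(lambda_grid, decreasing = TRUE),
                 standardize = FALSE, intercept = TRUE, thresh = 1e-10,
                 maxit = 1e6)
}

# Pick lambda by k-fold CV on (X, y); ties broken toward the larger
# (more conservative) penalty.
select_lambda <- function(X, y, lambda_grid, inner_folds, seed) {
  n <- nrow(X)
  k <- min(inner_folds, n)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  mse <- matrix(NA_real_, nrow = k, ncol = length(lambda_grid))
  grid_dec <- sort(lambda_grid, decreasing = TRUE)
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- ridge_path(X[!te, , drop = FALSE], y[!te], lambda_grid)
    pred <- stats::predict(fit, newx = X[te, , drop = FALSE], s = grid_dec)
    mse[f, ] <- colMeans((y[te] - pred)^2)
  }
  m <- colMeans(mse)
  grid_dec[which.min(m)]  # which.min takes the first = largest lambda on ties
}

#' Cross-validated ridge regression with nested penalty selection
#'
#' For every outer training fold, the ridge penalty is chosen from
#' `cfg$lambda_grid` by inner cross-validation on that fold alone
#' (`lambda_mode = "nested"`, the default, so penalty selection never
#' sees the held-out fold), or once on the full data
#' (`lambda_mode = "global"`). Reported coefficients always come from a
#' full-data fit at the full-data CV-selected penalty.
#'
#' @param X numeric `n x p` matrix of z-scored predictors, `p >= 2`.
#' @param y numeric response.
#' @param cfg a [cv_config()].
#' @param model_family label stored in the result.
#' @param inner_folds folds of the inner penalty-selection CV.
#' @param lambda_mode `"nested"` or `"global"`.
#' @return a `regression_result`.
#' @export
fit_ridge <- function(X, y, cfg, model_family = "sparsity_all",
                      inner_folds = 5L,
                      lambda_mode = c("nested", "global")) {
  stopifnot(inherits(cfg, "cv_config"), nrow(X) == length(y))
  lambda_mode <- match.arg(lambda_mode)
  if (ncol(X) < 2L) {
    stop("ridge battery models need p >= 2 predictors; use ",
         "fit_univariate() for a single predictor", call. = FALSE)
  }
  if (length(cfg$lambda_grid) == 0L) {
    stop("empty lambda grid", call. = FALSE)
  }
  n <- nrow(X)
  lambda_full <- select_lambda(X, y, cfg$lambda_grid, inner_folds,
                               derive_seed(cfg$seed, 999983L))
  scores <- matrix(NA_real_, nrow = cfg$folds, ncol = cfg$repeats)
  lambdas <- matrix(NA_real_, nrow = cfg$folds, ncol = cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    fold <- make_folds(n, cfg, r)
    for (f in seq_len(cfg$folds)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]
      ytr <- y[!te]
      lam <- if (lambda_mode == "nested") {
        select_lambda(Xtr, ytr, cfg$lambda_grid, inner_folds,
                      derive_seed(cfg$seed, 7000000L + r * 1000L + f))
      } else {
        lambda_full
      }
      fit <- ridge_path(Xtr, ytr, cfg$lambda_grid)
      pred <- stats::predict(fit, newx = X[te, , drop = FALSE], s = lam)
      scores[f, r] <- cv_r2(y[te], as.vector(pred))
      lambdas[f, r] <- lam
    }
  }
  r2 <- mean(colMeans(scores))
  full_fit <- ridge_path(X, y, cfg$lambda_grid)
  cf <- as.vector(stats::coef(full_fit, s = lambda_full))
  names(cf) <- c("intercept", colnames(X) %||% paste0("x", seq_len(ncol(X))))
  res <- new_regression_result(
    model_family, r2 = r2, r2_adjusted = adjusted_r2(r2, n, ncol(X)),
    coefficients = cf, per_fold_scores = scores,
    n_predictors = ncol(X), n = n, lambda = lambda_full
  )
  res$lambda_per_fold <- lambdas
  res
}

#' Permutation p-value of a cross-validated R-squared
#'
#' Permutes the response with a seeded generator and recomputes the CV
#' R-squared under each permutation;
#' `p = (1 + #\{R2_perm >= R2_obs\}) / (1 + B)`. Within the null, CV
#' uses a single repetition and (for ridge) the penalty is frozen at
#' the full-data CV-selected value of the observed fit, so the null
#' distribution is computable at realistic permutation counts.
#'
#' @param X predictor vector (univariate) or matrix (ridge).
#' @param y response vector.
#' @param cfg a [cv_config()].
#' @param model_family `"univariate"` or `"ridge"`.
#' @param observed observed CV R-squared; computed if `NULL`.
#' @param B permutation count; default `cfg$permutations`.
#' @param lambda frozen ridge penalty; full-data CV-selected if `NULL`.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(X, y, cfg,
                               model_family = c("univariate", "ridge"),
                               observed = NULL, B = cfg$permutations,
                               lambda = NULL) {
  stopifnot(inherits(cfg, "cv_config"), B >= 1L)
  model_family <- match.arg(model_family)
  n <- length(y)
  perm_cfg <- cv_config(folds = cfg$folds, repeats = 1L, seed = cfg$seed,
                        lambda_grid = cfg$lambda_grid, permutations = B)
  perms <- with_seed(derive_seed(cfg$seed, 424243L),
                     replicate(B, sample.int(n)))
  if (model_family == "univariate") {
    x <- as.vector(X)
    if (is.null(observed)) observed <- fit_univariate(x, y, cfg)$r2
    null_r2 <- cv_univariate_null(x, matrix(y[perms], nrow = n), perm_cfg)
  } else {
    X <- as.matrix(X)
    if (is.null(lambda)) {
      lambda <- select_lambda(X, y, cfg$lambda_grid, 5L,
                              derive_seed(cfg$seed, 999983L))
    }
    if (is.null(observed)) observed <- fit_ridge(X, y, cfg)$r2
    fold <- make_folds(n, perm_cfg, 1L)
    null_r2 <- vapply(seq_len(B), function(b) {
      yb <- y[perms[, b]]
      sc <- numeric(perm_cfg$folds)
      for (f in seq_len(perm_cfg$folds)) {
        te <- fold == f
        fit <- ridge_path(X[!te, , drop = FALSE], yb[!te], cfg$lambda_grid)
        pred <- stats::predict(fit, newx = X[te, , drop = FALSE], s = lambda)
        sc[f] <- cv_r2(yb[te], as.vector(pred))
      }
      mean(sc)
    }, numeric(1))
  }
  (1 + sum(null_r2 >= observed)) / (1 + B)
}

# Repeated-CV engine over an arbitrary design builder. `builder(tr, te)`
# returns list(tr = X_train, te = X_test) and may fit its own
# preprocessing (scaling, PCA) on the training rows only — this is the
# leakage-free evaluation path. Ridge with nested lambda selection for
# p >= 2, OLS for p = 1.
cv_builder_scores <- function(builder, y, cfg, inner_folds = 5L) {
  n <- length(y)
  scores <- matrix(NA_real_, nrow = cfg$folds, ncol = cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    fold <- make_folds(n, cfg, r)
    for (f in seq_len(cfg$folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      d <- builder(tr, te)
      pred <- if (ncol(d$tr) >= 2L) {
        lam <- select_lambda(d$tr, y[tr], cfg$lambda_grid, inner_folds,
                             derive_seed(cfg$seed, 7000000L + r * 1000L + f))
        fit <- ridge_path(d$tr, y[tr], cfg$lambda_grid)
        as.vector(stats::predict(fit, newx = d$te, s = lam))
      } else {
        cf <- ols_1d(d$tr[, 1L], y[tr])
        cf[1L] + cf[2L] * d$te[, 1L]
      }
      scores[f, r] <- cv_r2(y[te], pred)
    }
  }
  scores
}

# Column standardization fitted on training rows only.
scale_by_train <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sds <- apply(Xtr, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("degenerate input: constant training-fold column", call. = FALSE)
  }
  list(tr = sweep(sweep(Xtr, 2L, mu), 2L, sds, `/`),
       te = sweep(sweep(Xte, 2L, mu), 2L, sds, `/`))
}

# PCA fitted on training rows only; test rows projected.
pc_design_train <- function(A, tr, te, n_components = NULL,
                            variance_target = 0.80) {
  fm <- pca_retain(A[tr, , drop = FALSE], variance_target)
  k <- if (is.null(n_components)) fm$k else min(n_components, fm$k)
  rot <- fm$rotation[, seq_len(k), drop = FALSE]
  list(tr = fm$scores[, seq_len(k), drop = FALSE],
       te = sweep(A[te, , drop = FALSE], 2L, fm$center) %*% rot)
}

# Single-repeat univariate CV R-squared for every column of Y at once
# (vectorized over permutations).
cv_univariate_null <- function(x, Y, cfg) {
  n <- length(x)
  fold <- make_folds(n, cfg, 1L)
  acc <- matrix(NA_real_, nrow = cfg$folds, ncol = ncol(Y))
  for (f in seq_len(cfg$folds)) {
    te <- fold == f
    xtr <- x[!te]; xte <- x[te]
    Ytr <- Y[!te, , drop = FALSE]; Yte <- Y[te, , drop = FALSE]
    xc <- xtr - mean(xtr)
    slope <- as.vector(crossprod(xc, Ytr)) / sum(xc^2)
    intercept <- colMeans(Ytr) - slope * mean(xtr)
    pred <- outer(xte, slope) + matrix(intercept, nrow = length(xte),
                                       ncol = ncol(Y), byrow = TRUE)
    sse <- colSums((Yte - pred)^2)
    sst <- colSums(sweep(Yte, 2L, colMeans(Yte))^2)
    acc[f, ] <- 1 - sse / sst
  }
  colMeans(acc)
}

#' Run the five-family model battery
#'
#' Fits, on one dataset, the five model families of the analysis:
#' \enumerate{
#'   \item per-layer univariate regression on sparsity (one model per
#'     layer; the battery row reports the mean R-squared over layers);
#'   \item one ridge model on the sparsity of all layers;
#'   \item per-layer ridge on the retained principal components of that
#'     layer's activations (mean over layers);
#'   \item one global ridge on the first three PCs of every layer;
#'   \item one global ridge on the first three PCs plus the sparsity of
#'     every layer.
#' }
#'
#' @param sparsity `n_images x n_layers` matrix from
#'   [sparsity_profile()] (raw values; z-scoring happens here).
#' @param features named list of `feature_matrix` objects, one per
#'   layer, names matching `colnames(sparsity)`; may be `NULL` to fit
#'   the sparsity-only families alone.
#' @param y numeric beauty scores on the `[0, 5]` scale.
#' @param cfg a [cv_config()].
#' @param permutations permutation count for p-values; `0` skips
#'   significance testing (p-values `NA`).
#' @param preprocess `"full_data"` (default) fits the z-transform and
#'   PCA once on the complete dataset before cross-validation — the
#'   convention of the analysis this package implements, which leaks
#'   test information into preprocessing; `"fold_wise"` refits both
#'   inside every training fold (leakage-free evaluation; requires
#'   `activations` for the PC families, reports coefficients from
#'   full-data fits and no permutation p-values).
#' @param activations named list (one element per layer) of
#'   `n_images x d` activation matrices; only used by
#'   `preprocess = "fold_wise"`.
#' @return list with `battery` (one data.frame row per family:
#'   `family`, `n_predictors`, `r2`, `r2_adjusted`, `p_value`),
#'   `per_layer` (per-layer R-squared, univariate and all-layer-ridge
#'   coefficients, retained-component counts, p-values) and `details`
#'   (the underlying `regression_result` objects).
#' @export
run_model_battery <- function(sparsity, features, y, cfg,
                              permutations = 0L,
                              preprocess = c("full_data", "fold_wise"),
                              activations = NULL) {
  stopifnot(is.matrix(sparsity), nrow(sparsity) == length(y),
            inherits(cfg, "cv_config"))
  preprocess <- match.arg(preprocess)
  layers <- colnames(sparsity)
  if (!is.null(features)) {
    if (!setequal(names(features), layers)) {
      stop("layer mismatch between sparsity profile and feature ",
           "matrices", call. = FALSE)
    }
    features <- features[layers]
  }
  if (preprocess == "fold_wise") {
    return(battery_fold_wise(sparsity, activations, y, cfg, features))
  }
  S <- zscore_columns(sparsity)
  n <- length(y)
  L <- length(layers)

  # family 1: univariate per layer
  fam1 <- lapply(layers, function(l) {
    res <- fit_univariate(S[, l], y, cfg)
    if (permutations > 0L) {
      res$p_value <- permutation_pvalue(S[, l], y, cfg, "univariate",
                                        observed = res$r2, B = permutations)
    }
    res
  })
  names(fam1) <- layers

  # family 2: all-layer ridge on sparsity
  fam2 <- fit_ridge(S, y, cfg, model_family = "sparsity_all")
  if (permutations > 0L) {
    fam2$p_value <- permutation_pvalue(S, y, cfg, "ridge",
                                       observed = fam2$r2, B = permutations,
                                       lambda = fam2$lambda)
  }

  fam3 <- fam4 <- fam5 <- NULL
  if (!is.null(features)) {
    fam3 <- lapply(layers, function(l) {
      Z <- features[[l]]$scores
      res <- if (ncol(Z) >= 2L) {
        fit_ridge(zscore_columns(Z), y, cfg, model_family = "pc_per_layer")
      } else {
        fit_univariate(zscore_columns(Z)[, 1L], y, cfg,
                       model_family = "pc_per_layer")
      }
      if (permutations > 0L) {
        fam <- if (ncol(Z) >= 2L) "ridge" else "univariate"
        res$p_value <- permutation_pvalue(zscore_columns(Z), y, cfg, fam,
                                          observed = res$r2, B = permutations,
                                          lambda = res$lambda)
      }
      res
    })
    names(fam3) <- layers

    lead3 <- lapply(layers, function(l) {
      fm <- features[[l]]
      m <- first_k_scores(fm, min(3L, fm$k))
      colnames(m) <- paste0(l, "_pc", seq_len(ncol(m)))
      m
    })
    X4 <- zscore_columns(do.call(cbind, lead3))
    fam4 <- fit_ridge(X4, y, cfg, model_family = "pc_all3")
    X5 <- cbind(X4, S)
    fam5 <- fit_ridge(X5, y, cfg, model_family = "combined")
    if (permutations > 0L) {
      fam4$p_value <- permutation_pvalue(X4, y, cfg, "ridge",
                                         observed = fam4$r2, B = permutations,
                                         lambda = fam4$lambda)
      fam5$p_value <- permutation_pvalue(X5, y, cfg, "ridge",
                                         observed = fam5$r2, B = permutations,
                                         lambda = fam5$lambda)
    }
  }

  fam1_r2 <- vapply(fam1, `[[`, numeric(1), "r2")
  rows <- list(
    data.frame(family = "sparsity_per_layer", n_predictors = 1L,
               r2 = mean(fam1_r2), r2_adjusted = NA_real_,
               p_value = NA_real_),
    data.frame(family = "sparsity_all", n_predictors = L,
               r2 = fam2$r2, r2_adjusted = fam2$r2_adjusted,
               p_value = fam2$p_value)
  )
  if (!is.null(features)) {
    fam3_r2 <- vapply(fam3, `[[`, numeric(1), "r2")
    rows <- c(rows, list(
      data.frame(family = "pc_per_layer", n_predictors = NA_integer_,
                 r2 = mean(fam3_r2), r2_adjusted = NA_real_,
                 p_value = NA_real_),
      data.frame(family = "pc_all3", n_predictors = fam4$n_predictors,
                 r2 = fam4$r2, r2_adjusted = fam4$r2_adjusted,
                 p_value = fam4$p_value),
      data.frame(family = "combined", n_predictors = fam5$n_predictors,
                 r2 = fam5$r2, r2_adjusted = fam5$r2_adjusted,
                 p_value = fam5$p_value)
    ))
  }
  battery <- do.call(rbind, rows)

  per_layer <- data.frame(
    layer_id = layers,
    r2_sparsity = unname(fam1_r2),
    coef_univariate = vapply(fam1, function(r) r$coefficients[["slope"]],
                             numeric(1)),
    coef_ridge_all = unname(fam2$coefficients[layers]),
    p_value = vapply(fam1, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  if (!is.null(features)) {
    per_layer$r2_pc <- unname(fam3_r2)
    per_layer$k_retained <- unname(vapply(features, `[[`, integer(1), "k"))
  }
  rownames(per_layer) <- NULL

  list(battery = battery, per_layer = per_layer,
       details = list(sparsity_per_layer = fam1, sparsity_all = fam2,
                      pc_per_layer = fam3, pc_all3 = fam4, combined = fam5),
       config = cfg)
}

# Leakage-free battery: standardization and PCA are refit inside every
# training fold (cv_builder_scores / scale_by_train / pc_design_train).
# Coefficients still come from full-data fits (fold-wise coefficients
# are not uniquely defined); permutation p-values are not computed in
# this mode.
battery_fold_wise <- function(sparsity, activations, y, cfg, features) {
  layers <- colnames(sparsity)
  n <- length(y)
  L <- length(layers)
  if (!is.null(activations)) {
    if (!setequal(names(activations), layers)) {
      stop("layer mismatch between sparsity profile and activation ",
           "matrices", call. = FALSE)
    }
    activations <- activations[layers]
    stopifnot(all(vapply(activations, nrow, 0L) == n))
  }

  mean_r2 <- function(scores) mean(colMeans(scores))

  # family 1: univariate per layer (OLS predictions are invariant to
  # the predictor's affine scaling, so this family is leakage-free in
  # either mode)
  fam1_scores <- lapply(layers, function(l) {
    cv_builder_scores(function(tr, te) {
      list(tr = sparsity[tr, l, drop = FALSE],
           te = sparsity[te, l, drop = FALSE])
    }, y, cfg)
  })
  fam1_r2 <- vapply(fam1_scores, mean_r2, numeric(1))

  # family 2: all-layer ridge, fold-wise z-scoring
  fam2_scores <- cv_builder_scores(function(tr, te) {
    scale_by_train(sparsity[tr, , drop = FALSE],
                   sparsity[te, , drop = FALSE])
  }, y, cfg)
  fam2_r2 <- mean_r2(fam2_scores)

  fam3_r2 <- fam4_r2 <- fam5_r2 <- NULL
  fam3_scores <- fam4_scores <- fam5_scores <- NULL
  if (!is.null(activations)) {
    fam3_scores <- lapply(layers, function(l) {
      cv_builder_scores(function(tr, te) {
        d <- pc_design_train(activations[[l]], tr, te)
        if (ncol(d$tr) >= 2L) scale_by_train(d$tr, d$te) else d
      }, y, cfg)
    })
    fam3_r2 <- vapply(fam3_scores, mean_r2, numeric(1))

    lead3_design <- function(tr, te) {
      parts <- lapply(activations, pc_design_train, tr = tr, te = te,
                      n_components = 3L)
      list(tr = do.call(cbind, lapply(parts, `[[`, "tr")),
           te = do.call(cbind, lapply(parts, `[[`, "te")))
    }
    fam4_scores <- cv_builder_scores(function(tr, te) {
      d <- lead3_design(tr, te)
      scale_by_train(d$tr, d$te)
    }, y, cfg)
    fam4_r2 <- mean_r2(fam4_scores)

    fam5_scores <- cv_builder_scores(function(tr, te) {
      d <- lead3_design(tr, te)
      scale_by_train(cbind(d$tr, sparsity[tr, , drop = FALSE]),
                     cbind(d$te, sparsity[te, , drop = FALSE]))
    }, y, cfg)
    fam5_r2 <- mean_r2(fam5_scores)
  }

  # coefficients from full-data fits, as in the default mode
  S <- zscore_columns(sparsity)
  coef_uni <- vapply(layers, function(l) ols_1d(S[, l], y)[2L], numeric(1))
  lambda_full <- select_lambda(S, y, cfg$lambda_grid, 5L,
                               derive_seed(cfg$seed, 999983L))
  cf2 <- as.vector(stats::coef(ridge_path(S, y, cfg$lambda_grid),
                               s = lambda_full))[-1L]

  rows <- list(
    data.frame(family = "sparsity_per_layer", n_predictors = 1L,
               r2 = mean(fam1_r2), r2_adjusted = NA_real_,
               p_value = NA_real_),
    data.frame(family = "sparsity_all", n_predictors = L,
               r2 = fam2_r2, r2_adjusted = adjusted_r2(fam2_r2, n, L),
               p_value = NA_real_)
  )
  if (!is.null(activations)) {
    p4 <- if (!is.null(features)) {
      sum(vapply(features, function(f) min(3L, f$k), integer(1)))
    } else {
      NA_integer_
    }
    rows <- c(rows, list(
      data.frame(family = "pc_per_layer", n_predictors = NA_integer_,
                 r2 = mean(fam3_r2), r2_adjusted = NA_real_,
                 p_value = NA_real_),
      data.frame(family = "pc_all3", n_predictors = p4,
                 r2 = fam4_r2,
                 r2_adjusted = if (is.na(p4)) NA_real_ else
                   adjusted_r2(fam4_r2, n, p4),
                 p_value = NA_real_),
      data.frame(family = "combined", n_predictors = p4 + L,
                 r2 = fam5_r2,
                 r2_adjusted = if (is.na(p4)) NA_real_ else
                   adjusted_r2(fam5_r2, n, p4 + L),
                 p_value = NA_real_)
    ))
  }
  per_layer <- data.frame(
    layer_id = layers, r2_sparsity = unname(fam1_r2),
    coef_univariate = unname(coef_uni), coef_ridge_all = cf2,
    p_value = NA_real_, stringsAsFactors = FALSE
  )
  if (!is.null(activations)) {
    per_layer$r2_pc <- unname(fam3_r2)
    per_layer$k_retained <- if (!is.null(features)) {
      unname(vapply(features, `[[`, integer(1), "k"))
    } else {
      NA_integer_
    }
  }
  list(battery = do.call(rbind, rows), per_layer = per_layer,
       details = list(preprocess = "fold_wise",
                      per_fold = list(sparsity_per_layer = fam1_scores,
                                      sparsity_all = fam2_scores,
                                      pc_per_layer = fam3_scores,
                                      pc_all3 = fam4_scores,
                                      combined = fam5_scores)),
       config = cfg)
}
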