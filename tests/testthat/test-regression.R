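test_that("fold assignment is a deterministic near-equal partition", {
  cfg <- cv_config(folds = 10L, repeats = 2L, seed = 17L)
  f <- make_folds(100L, cfg, 1L)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(tabulate(f, 10L) == 10L))
  expect_identical(f, make_folds(100L, cfg, 1L))
  expect_false(identical(f, make_folds(100L, cfg, 2L)))
  # uneven n still covers every index exactly once
  f2 <- make_folds(23L, cfg, 1L)
  expect_identical(length(f2), 23L)
  expect_true(all(tabulate(f2, 10L) %in% 2:3))
  expect_error(make_folds(5L, cfg), "folds")
})

test_that("univariate CV regression recovers signal and respects the null", {
  cfg <- cv_config(folds = 10L, repeats = 3L, seed = 21L)
  set.seed(1)
  x <- as.vector(zscore_columns(matrix(rnorm(200), ncol = 1L)))
  res <- fit_univariate(x, 2 * x, cfg)
  expect_gte(res$r2, 0.999)
  expect_equal(unname(res$coefficients["slope"]), 2, tolerance = 1e-10)
  expect_identical(dim(res$per_fold_scores), c(10L, 3L))
  # null: y independent of x, large n, many repeats
  cfg100 <- cv_config(folds = 10L, repeats = 100L, seed = 22L)
  set.seed(2)
  xn <- rnorm(1000)
  yn <- rnorm(1000)
  rn <- fit_univariate(xn, yn, cfg100)
  expect_gte(rn$r2, -0.02)
  expect_lte(rn$r2, 0.01)
  # population R2 = 0.5 by construction
  set.seed(3)
  x5 <- as.vector(zscore_columns(matrix(rnorm(2000), ncol = 1L)))
  y5 <- x5 + rnorm(2000)
  r5 <- fit_univariate(x5, y5, cfg)
  expect_gte(r5$r2, 0.45)
  expect_lte(r5$r2, 0.55)
  expect_error(fit_univariate(rep(1, 50), rnorm(50), cfg), "zero variance")
})

test_that("ridge recovers OLS at vanishing penalty and shrinks to the mean", {
  set.seed(4)
  X <- zscore_columns(matrix(rnorm(200 * 5), 200L, 5L))
  colnames(X) <- paste0("v", 1:5)
  y <- as.vector(X %*% c(1, -1, 0.5, 0, 2)) + rnorm(200, sd = 0.5)
  tiny <- cv_config(folds = 10L, repeats = 2L, seed = 5L, lambda_grid = 1e-8)
  r_tiny <- fit_ridge(X, y, tiny)
  expect_lt(max(abs(r_tiny$coefficients - coef(lm(y ~ X)))), 1e-4)
  huge <- cv_config(folds = 10L, repeats = 2L, seed = 5L, lambda_grid = 1e8)
  r_huge <- fit_ridge(X, y, huge)
  expect_lt(max(abs(r_huge$coefficients[-1L])), 1e-4)
  expect_lte(r_huge$r2, 0)
  expect_error(fit_ridge(X, y, cv_config(lambda_grid = numeric())), "lambda")
  expect_error(fit_ridge(X[, 1L, drop = FALSE], y, tiny), "p >= 2")
})

test_that("ridge results are deterministic and R2 is affine-invariant in y", {
  study <- make_sparsity_study(150L, n_layers = 4L, seed = 51L)
  S <- zscore_columns(study$prof)
  y <- study$sim$scores
  cfg <- cv_config(folds = 10L, repeats = 2L, seed = 6L)
  a <- fit_ridge(S, y, cfg)
  b <- fit_ridge(S, y, cfg)
  expect_identical(a$per_fold_scores, b$per_fold_scores)
  expect_identical(a$coefficients, b$coefficients)
  # affine rescaling of the response leaves R2 unchanged (up to the
  # iterative ridge solver's convergence tolerance)
  shifted <- fit_ridge(S, 3 + 0.4 * y, cfg)
  expect_equal(shifted$r2, a$r2, tolerance = 1e-3)
  u <- fit_univariate(S[, 1L], y, cfg)
  u2 <- fit_univariate(S[, 1L], 3 + 0.4 * y, cfg)
  expect_equal(u2$r2, u$r2, tolerance = 1e-10)
})

test_that("permutation p-values are seeded, minimal for perfect signal, valid", {
  cfg <- cv_config(folds = 10L, repeats = 1L, seed = 77L)
  set.seed(7)
  x <- as.vector(zscore_columns(matrix(rnorm(100), ncol = 1L)))
  p_perfect <- permutation_pvalue(x, 2 * x, cfg, "univariate", B = 999L)
  expect_equal(p_perfect, 1 / 1000)
  expect_identical(permutation_pvalue(x, 2 * x, cfg, "univariate", B = 99L),
                   permutation_pvalue(x, 2 * x, cfg, "univariate", B = 99L))
  # ridge flavour: strong multivariate signal is detected
  study <- make_sparsity_study(120L, n_layers = 4L, target_r2 = 0.6,
                               seed = 52L)
  S <- zscore_columns(study$prof)
  p_ridge <- permutation_pvalue(S, study$sim$scores, cfg, "ridge", B = 99L)
  expect_equal(p_ridge, 1 / 100)
})

test_that("the battery builds the five families with the right designs", {
  study <- make_sparsity_study(60L, n_layers = 4L, seed = 3L,
                               target_r2 = 0.6)
  feats <- make_features(study$acts)
  cfg <- cv_config(folds = 10L, repeats = 2L, seed = 8L)
  bat <- run_model_battery(study$prof, feats, study$sim$scores, cfg)
  expect_identical(bat$battery$family,
                   c("sparsity_per_layer", "sparsity_all", "pc_per_layer",
                     "pc_all3", "combined"))
  # predictor counts follow the construction rule at 4 layers
  expect_identical(bat$battery$n_predictors[c(1L, 2L, 4L, 5L)],
                   c(1L, 4L, 12L, 16L))
  expect_identical(bat$details$combined$n_predictors,
                   bat$details$pc_all3$n_predictors + 4L)
  expect_identical(nrow(bat$per_layer), 4L)
  expect_identical(bat$per_layer$k_retained,
                   unname(vapply(feats, `[[`, integer(1), "k")))
  # per-layer coefficients reported in both modes
  expect_true(all(c("coef_univariate", "coef_ridge_all") %in%
                    names(bat$per_layer)))
  # mean-over-layers battery rows match the per-layer details
  expect_equal(bat$battery$r2[1L], mean(bat$per_layer$r2_sparsity))
  # layer mismatch between profile and features is a configuration error
  bad <- feats
  names(bad)[1L] <- "layer_X"
  expect_error(run_model_battery(study$prof, bad, study$sim$scores, cfg),
               "mismatch")
})

test_that("sparsity-driven data favours sparsity models; combining is safe", {
  study <- make_sparsity_study(500L, n_layers = 4L, seed = 13L,
                               target_r2 = 0.5)
  feats <- make_features(study$acts)
  cfg <- cv_config(folds = 10L, repeats = 3L, seed = 8L)
  bat <- run_model_battery(study$prof, feats, study$sim$scores, cfg)
  r2 <- setNames(bat$battery$r2, bat$battery$family)
  # all signal lives in sparsity: family 2 clearly beats family 4
  expect_gte(r2[["sparsity_all"]], r2[["pc_all3"]] + 0.1)
  # adding predictors under a tuned penalty cannot badly hurt held-out fit
  expect_gte(r2[["combined"]], r2[["sparsity_all"]] - 0.05)
  expect_gte(r2[["combined"]], r2[["pc_all3"]] - 0.05)
})

test_that("fold-wise preprocessing gives a leakage-free battery", {
  study <- make_sparsity_study(120L, n_layers = 4L, seed = 61L,
                               target_r2 = 0.5)
  feats <- make_features(study$acts)
  acts_mat <- lapply(names(study$acts[[1L]]), function(l) {
    t(vapply(study$acts, function(a) a[[l]],
             numeric(length(study$acts[[1L]][[l]]))))
  })
  names(acts_mat) <- names(study$acts[[1L]])
  cfg <- cv_config(folds = 10L, repeats = 2L, seed = 8L)
  full <- run_model_battery(study$prof, feats, study$sim$scores, cfg)
  fw <- run_model_battery(study$prof, feats, study$sim$scores, cfg,
                          preprocess = "fold_wise",
                          activations = acts_mat)
  expect_identical(fw$battery$family, full$battery$family)
  expect_identical(fw$battery$n_predictors[c(1L, 2L, 5L)],
                   c(1L, 4L, full$battery$n_predictors[4L] + 4L))
  expect_true(all(is.finite(fw$battery$r2)))
  # family 1 is invariant to where the z-transform is fit (OLS is
  # affine-equivariant), so the two modes agree exactly there
  expect_equal(fw$per_layer$r2_sparsity, full$per_layer$r2_sparsity,
               tolerance = 1e-10)
  # fitting preprocessing on the full data cannot look worse than the
  # leakage-free evaluation, beyond CV noise
  expect_lte(fw$battery$r2[2L], full$battery$r2[2L] + 0.05)
  # full-data coefficients are shared between the modes
  expect_equal(fw$per_layer$coef_ridge_all, full$per_layer$coef_ridge_all,
               tolerance = 1e-8)
  # deterministic
  fw2 <- run_model_battery(study$prof, feats, study$sim$scores, cfg,
                           preprocess = "fold_wise",
                           activations = acts_mat)
  expect_identical(fw$battery, fw2$battery)
})
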