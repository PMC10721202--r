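test_that("synthetic config validates its contract", {
  expect_error(synthetic_config(10L, noise_sd = 1, target_r2 = 0.5),
               "exactly one")
  expect_error(synthetic_config(10L), "exactly one")
  expect_error(synthetic_config(10L, target_r2 = 1.2), "target_r2")
  expect_error(synthetic_config(10L, n_layers = 2L, layer_sizes = 1L,
                                noise_sd = 1), "layer_sizes")
  expect_error(synthetic_config(10L, noise_sd = 1,
                                gamma_shape_range = c(2, 1)),
               "gamma_shape_range")
  expect_error(synthetic_config(10L, n_layers = 3L, beta = c(1, 2),
                                noise_sd = 1), "beta")
})

test_that("activation generation is seeded, non-negative, shape-controlled", {
  cfg <- synthetic_config(20L, n_layers = 3L, layer_sizes = c(50L, 30L, 10L),
                          beta = c(1, -1, 1), noise_sd = 1, seed = 9L)
  a1 <- generate_activations(cfg)
  a2 <- generate_activations(cfg)
  expect_identical(a1, a2)
  expect_length(a1, 20L)
  expect_identical(lengths(a1[[1L]]), c(layer_1 = 50L, layer_2 = 30L,
                                        layer_3 = 10L))
  expect_true(all(unlist(a1) >= 0))
  shapes <- attr(a1, "shapes")
  expect_true(all(shapes >= 0.5 & shapes <= 5))
  a3 <- generate_activations(synthetic_config(20L, n_layers = 3L,
                                              layer_sizes = c(50L, 30L, 10L),
                                              beta = c(1, -1, 1),
                                              noise_sd = 1, seed = 10L))
  expect_false(identical(a1, a3))
})

test_that("gamma shape controls Gini as the closed form predicts", {
  # population Gini of Gamma(k, 1) is Gamma(k + 1/2)/(Gamma(k + 1) sqrt(pi));
  # 0.5 at k = 1 (exponential). Checked with the pairwise oracle so the
  # anchor does not depend on the sorted-formula implementation.
  cfg <- synthetic_config(1L, n_layers = 1L, layer_sizes = 100000L,
                          beta = 1, noise_sd = 1,
                          gamma_shape_range = c(1, 1), seed = 30L)
  x <- generate_activations(cfg)[[1L]][[1L]]
  set.seed(31)
  sub_gini <- replicate(60, {
    gini_pairwise_oracle(x[sample.int(length(x), 300L)])
  })
  expect_equal(mean(sub_gini), 0.5, tolerance = 0.01)
  # smaller shape => sparser code, essentially always
  set.seed(32)
  wins <- sum(replicate(100, {
    gini_index(rgamma(500L, shape = 0.2)) > gini_index(rgamma(500L, shape = 5))
  }))
  expect_gte(wins, 99L)
})

test_that("score simulation honours the population-R2 identity", {
  study <- make_sparsity_study(2000L, n_layers = 15L, layer_sizes = 256L,
                               target_r2 = 0.25, seed = 9L)
  sim <- study$sim
  realized <- var(sim$signal) / var(sim$y_star)
  expect_gte(realized, 0.21)
  expect_lte(realized, 0.29)
  expect_true(all(sim$scores >= 0 & sim$scores <= 5))
  # the affine map is recorded and invertible
  expect_equal((sim$scores / sim$map$slope) + sim$map$offset, sim$y_star,
               tolerance = 1e-10)
  # noiseless scores are an exact affine function of the signal
  cfg0 <- synthetic_config(100L, n_layers = 4L, beta = default_beta(4L),
                           noise_sd = 0, seed = 12L)
  S <- zscore_columns(sparsity_profile(generate_activations(cfg0), "gini"))
  sim0 <- simulate_scores(S, cfg0)
  expect_equal(sim0$y_star, sim0$signal)
  expect_equal(sim0$scores, (sim0$signal - sim0$map$offset) * sim0$map$slope)
  # downstream: the noiseless all-layer model is essentially exact
  rr0 <- fit_ridge(S, sim0$scores, cv_config(folds = 10L, repeats = 2L,
                                             seed = 13L))
  expect_gte(rr0$r2, 0.99)
  # mismatched beta length is a configuration error
  expect_error(simulate_scores(S[, 1:3], cfg0), "beta length")
})

test_that("null scores are independent of sparsity", {
  cfg <- synthetic_config(2000L, n_layers = 15L, layer_sizes = 256L,
                          beta = rep(0, 15L), noise_sd = 1, seed = 33L)
  S <- zscore_columns(sparsity_profile(generate_activations(cfg), "gini"))
  sim <- simulate_scores(S, cfg)
  rr <- fit_ridge(S, sim$scores, cv_config(folds = 10L, repeats = 5L,
                                           seed = 44L))
  expect_gte(rr$r2, -0.03)
  expect_lte(rr$r2, 0.02)
})

test_that("fixture images are deterministic, decodable, class-separated", {
  d <- withr::local_tempdir()
  p1 <- generate_fixture_images(5L, "sparse_dots", seed = 7L,
                                dir = file.path(d, "a"))
  expect_length(p1, 5L)
  expect_true(all(file.exists(p1)))
  px <- png::readPNG(p1[1L])
  expect_identical(dim(px), c(32L, 32L, 3L))
  p2 <- generate_fixture_images(5L, "sparse_dots", seed = 7L,
                                dir = file.path(d, "b"))
  expect_identical(png::readPNG(p2[3L]), png::readPNG(p1[3L]))
  p3 <- generate_fixture_images(5L, "dense_noise", seed = 7L,
                                dir = file.path(d, "c"))
  expect_false(identical(png::readPNG(p3[1L]), px))
  # sparse stimuli yield sparser first-layer codes under the fixture net
  fb <- fixture_backend(42L)
  g <- function(paths) {
    vapply(paths, function(p) {
      gini_index(extract_layer_activations(preprocess_image(p, fb), fb,
                                           layers = "conv1")$conv1)
    }, numeric(1))
  }
  ps <- generate_fixture_images(15L, "sparse_dots", seed = 8L,
                                dir = file.path(d, "s"))
  pd <- generate_fixture_images(15L, "dense_noise", seed = 8L,
                                dir = file.path(d, "n"))
  expect_gt(median(g(ps)), median(g(pd)))
})
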