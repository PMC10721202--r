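# Random non-negative activation-like vectors mixing heavy and light
# tails, including exact zeros (post-ReLU codes are zero-inflated).
rand_nonneg_vector <- function(n) {
  src <- sample(1:3, 1L)
  x <- switch(src,
              rexp(n),
              rgamma(n, shape = runif(1, 0.2, 5)),
              runif(n))
  zeros <- runif(n) < runif(1, 0, 0.5)
  x[zeros] <- 0
  if (all(x == 0)) x[1L] <- 1
  x
}

# Small synthetic study shared by regression/battery tests: gamma
# activations for `n_layers` layers, sparsity-driven scores.
make_sparsity_study <- function(n_images, n_layers = 4L, layer_sizes = 40L,
                                target_r2 = 0.5, seed = 13L,
                                beta = default_beta(n_layers)) {
  cfg <- synthetic_config(n_images = n_images, n_layers = n_layers,
                          layer_sizes = layer_sizes, beta = beta,
                          target_r2 = target_r2, seed = seed)
  acts <- generate_activations(cfg)
  prof <- sparsity_profile(acts, "gini")
  sim <- simulate_scores(zscore_columns(prof), cfg)
  list(cfg = cfg, acts = acts, prof = prof, sim = sim)
}

# Per-layer PCA feature matrices from a generated activation set.
make_features <- function(acts, variance_target = 0.80) {
  layers <- names(acts[[1L]])
  feats <- lapply(layers, function(l) {
    A <- t(vapply(acts, function(a) a[[l]],
                  numeric(length(acts[[1L]][[l]]))))
    pca_retain(A, variance_target, layer_id = l)
  })
  names(feats) <- layers
  feats
}
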