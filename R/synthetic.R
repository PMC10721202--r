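#' Synthetic data with known ground truth
#'
#' Download-free inputs carrying the statistical structure the analysis
#' assumes: per-image per-layer non-negative activation vectors whose
#' sparsity is controllable, rating scores generated from a known
#' linear combination of layer sparsities plus Gaussian noise, and
#' small raster images driving the fixture encoder end to end. The
#' Gamma family generates activations because its population Gini index
#' has a closed form, `Gini = Gamma(k + 1/2) / (Gamma(k + 1) sqrt(pi))`
#' (0.5 at shape k = 1, i.e. the exponential), giving analytic anchors
#' that do not depend on the implementation under test. Smaller shapes
#' give sparser codes.
#'
#' @name synthetic-data
NULL

#' Configuration of the synthetic study
#'
#' Defaults describe the reference synthetic study: 15 layers (the
#' measured depth of the VGG16 plan) of 256 activations each, per-layer
#' coefficients of alternating sign with magnitudes spread over
#' `[0.5, 1.5]` score units per SD of sparsity, gamma shapes in
#' `[0.5, 5]` (population Gini roughly 0.62 down to 0.23), and a
#' cross-layer sparsity correlation induced by a shared per-image
#' latent shape factor with weight 0.5.
#'
#' @param n_images number of simulated images.
#' @param n_layers number of layers.
#' @param layer_sizes activation counts per layer (recycled to
#'   `n_layers`; each >= 2).
#' @param beta per-layer true coefficients (score units per SD of
#'   sparsity); default [default_beta()].
#' @param noise_sd Gaussian noise SD of the score model; exactly one of
#'   `noise_sd` / `target_r2` must be given.
#' @param target_r2 population R-squared of the score model in (0, 1);
#'   sets `noise_sd` through the identity
#'   `R2 = Var(S beta) / (Var(S beta) + sigma^2)`.
#' @param gamma_shape_range range of per-image-per-layer gamma shapes.
#' @param layer_cor weight in `[0, 1)` of the shared per-image latent
#'   controlling how correlated layer sparsities are.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_images, n_layers = 15L,
                             layer_sizes = 256L,
                             beta = default_beta(n_layers),
                             noise_sd = NULL, target_r2 = NULL,
                             gamma_shape_range = c(0.5, 5),
                             layer_cor = 0.5, seed = 1L) {
  if (is.null(noise_sd) == is.null(target_r2)) {
    stop("exactly one of noise_sd / target_r2 must be set", call. = FALSE)
  }
  if (!is.null(target_r2) && (target_r2 <= 0 || target_r2 >= 1)) {
    stop("target_r2 must lie in (0, 1)", call. = FALSE)
  }
  layer_sizes <- rep_len(as.integer(layer_sizes), n_layers)
  if (any(layer_sizes < 2L)) {
    stop("layer_sizes entries must be >= 2", call. = FALSE)
  }
  if (length(beta) != n_layers) {
    stop("beta must have one coefficient per layer", call. = FALSE)
  }
  if (length(gamma_shape_range) != 2L || any(gamma_shape_range <= 0) ||
      diff(gamma_shape_range) < 0) {
    stop("gamma_shape_range must be two positive increasing values",
         call. = FALSE)
  }
  stopifnot(layer_cor >= 0, layer_cor < 1)
  structure(
    list(n_images = as.integer(n_images), n_layers = as.integer(n_layers),
         layer_sizes = layer_sizes, beta = as.numeric(beta),
         noise_sd = noise_sd, target_r2 = target_r2,
         gamma_shape_range = as.numeric(gamma_shape_range),
         layer_cor = layer_cor, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default per-layer true coefficients
#'
#' Alternating-sign coefficients with magnitudes spread evenly over
#' `[0.5, 1.5]` score units per SD of sparsity: every layer matters,
#' signs are mixed (as the per-layer coefficients of the real analysis
#' are), and magnitudes are distinguishable in recovery checks.
#'
#' @param n_layers number of layers.
#' @return numeric vector of length `n_layers`.
#' @export
default_beta <- function(n_layers) {
  mag <- if (n_layers == 1L) 1 else seq(0.5, 1.5, length.out = n_layers)
  mag * rep_len(c(1, -1), n_layers)
}

#' Generate per-image per-layer activation vectors
#'
#' For image `i` and layer `l`, activations are iid draws from
#' `Gamma(shape = k_il, scale = 1)` with
#' `k_il = k_min + (k_max - k_min) * (rho * u_i + (1 - rho) * v_il)`,
#' where `u_i` is a per-image latent and `v_il` an independent uniform;
#' `rho = layer_cor` makes the sparsities of different layers of the
#' same image correlated, as they are under a real encoder. Smaller
#' shape means higher Gini. Fully determined by `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list over images (`img_1`, ...) of named lists over layers
#'   (`layer_1`, ...) of non-negative activation vectors; the shape
#'   matrix is attached as `attr(, "shapes")`.
#' @export
generate_activations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  k_min <- cfg$gamma_shape_range[1L]
  k_max <- cfg$gamma_shape_range[2L]
  rho <- cfg$layer_cor
  with_seed(derive_seed(cfg$seed, 1L), {
    u <- stats::runif(cfg$n_images)
    shapes <- matrix(NA_real_, cfg$n_images, cfg$n_layers)
    out <- vector("list", cfg$n_images)
    for (i in seq_len(cfg$n_images)) {
      v <- stats::runif(cfg$n_layers)
      k_il <- k_min + (k_max - k_min) * (rho * u[i] + (1 - rho) * v)
      shapes[i, ] <- k_il
      img <- vector("list", cfg$n_layers)
      for (l in seq_len(cfg$n_layers)) {
        img[[l]] <- stats::rgamma(cfg$layer_sizes[l], shape = k_il[l],
                                  scale = 1)
      }
      names(img) <- paste0("layer_", seq_len(cfg$n_layers))
      out[[i]] <- img
    }
    names(out) <- paste0("img_", seq_len(cfg$n_images))
    attr(out, "shapes") <- shapes
    out
  })
}

#' Simulate rating scores from a sparsity matrix
#'
#' Generates `y* = S beta + eps`, `eps ~ N(0, noise_sd^2)` (seeded),
#' then maps `y*` affinely onto `[0, 5]` (min to 0, max to 5; affine
#' rather than clipped so the linear generative model that recovery
#' checks rely on is preserved — R-squared is invariant to the map).
#' With `target_r2` set, the noise SD is
#' `sqrt(Var(S beta) (1 - R2) / R2)` with the realized sample variance
#' of the signal.
#'
#' @param S `n x L` z-scored sparsity matrix.
#' @param cfg a [synthetic_config()] with `beta` of length `L`.
#' @return list with `scores` (in `[0, 5]`), `y_star` (unmapped),
#'   `signal` (`S beta`), `noise_sd`, `beta`, and `map`
#'   (`offset`, `slope` of the affine rescaling).
#' @export
simulate_scores <- function(S, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), is.matrix(S))
  if (ncol(S) != length(cfg$beta)) {
    stop("beta length (", length(cfg$beta), ") does not match the ",
         "number of sparsity columns (", ncol(S), ")", call. = FALSE)
  }
  signal <- as.vector(S %*% cfg$beta)
  noise_sd <- cfg$noise_sd %||%
    sqrt(stats::var(signal) * (1 - cfg$target_r2) / cfg$target_r2)
  eps <- with_seed(derive_seed(cfg$seed, 2L),
                   stats::rnorm(nrow(S), sd = noise_sd))
  y_star <- signal + eps
  rng <- range(y_star)
  slope <- if (diff(rng) > 0) 5 / diff(rng) else 0
  scores <- (y_star - rng[1L]) * slope
  list(scores = scores, y_star = y_star, signal = signal,
       noise_sd = noise_sd, beta = cfg$beta,
       map = list(offset = rng[1L], slope = slope))
}

#' Generate fixture images
#'
#' Writes seeded, deterministic 32x32 RGB PNG images of two classes:
#' `sparse_dots` (a few bright Gaussian blobs on black — sparse
#' stimuli yielding sparse early-layer codes) and `dense_noise`
#' (full-field uniform noise).
#'
#' @param n number of images (>= 1).
#' @param sparsity_class `"sparse_dots"` or `"dense_noise"`.
#' @param seed integer seed.
#' @param dir output directory, created if needed.
#' @return character vector of the PNG paths written.
#' @export
generate_fixture_images <- function(n, sparsity_class = c("sparse_dots",
                                                          "dense_noise"),
                                    seed = 1L, dir = tempdir()) {
  sparsity_class <- match.arg(sparsity_class)
  stopifnot(n >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  side <- 32L
  paths <- file.path(dir, sprintf("%s_%04d.png", sparsity_class, seq_len(n)))
  with_seed(derive_seed(seed, 3L), {
    for (i in seq_len(n)) {
      img <- array(0, dim = c(side, side, 3L))
      if (sparsity_class == "dense_noise") {
        img[] <- stats::runif(side * side * 3L)
      } else {
        n_blobs <- sample(1:3, 1L)
        gx <- matrix(rep(seq_len(side), side), side, side)
        gy <- t(gx)
        for (b in seq_len(n_blobs)) {
          cx <- stats::runif(1, 4, side - 3)
          cy <- stats::runif(1, 4, side - 3)
          sigma <- stats::runif(1, 1, 2)
          blob <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
          col <- stats::runif(3, 0.6, 1)
          for (c in 1:3) {
            img[, , c] <- pmin(1, img[, , c] + col[c] * blob)
          }
        }
      }
      png::writePNG(img, paths[i])
    }
  })
  paths
}

#' Simulate a complete fixture-encoder study
#'
#' End-to-end test harness: generates `n` images (half `sparse_dots`,
#' half `dense_noise`), assigns class-dependent scores
#' (`sparse_dots ~ N(4, 0.3)`, `dense_noise ~ N(1.5, 0.3)`, truncated
#' to `[0, 5]`), and returns image paths, class labels and scores. Runs
#' everything downstream of the encoder against stimuli whose
#' early-layer code sparsity genuinely differs.
#'
#' @param n total number of images (split evenly between classes).
#' @param seed integer seed.
#' @param dir image output directory.
#' @return list with `paths`, `class`, `scores`.
#' @export
simulate_fixture_study <- function(n = 200L, seed = 1L, dir = tempdir()) {
  n1 <- n %/% 2L
  n2 <- n - n1
  p1 <- generate_fixture_images(n1, "sparse_dots", seed = seed,
                                dir = file.path(dir, "sparse_dots"))
  p2 <- generate_fixture_images(n2, "dense_noise", seed = seed + 1L,
                                dir = file.path(dir, "dense_noise"))
  scores <- with_seed(derive_seed(seed, 4L), {
    pmin(5, pmax(0, c(stats::rnorm(n1, 4, 0.3), stats::rnorm(n2, 1.5, 0.3))))
  })
  list(paths = c(p1, p2),
       class = rep(c("sparse_dots", "dense_noise"), c(n1, n2)),
       scores = scores)
}
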