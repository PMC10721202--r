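test_that("VGG16 adapter declares the 15-layer measurement plan", {
  b <- vgg16_backend()
  expect_length(b$layer_specs, 15L)
  kinds <- vapply(b$layer_specs, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "convolution"), 13L)
  expect_identical(sum(kinds == "fully_connected"), 2L)
  ll <- layer_lengths(b)
  expect_identical(ll[["conv1_1"]], 224 * 224 * 64)
  expect_identical(ll[["fc1"]], 4096)
  expect_identical(ll[["fc2"]], 4096)
  hw <- vapply(b$layer_specs[1:13], function(s) s$shape[1L], integer(1))
  ch <- vapply(b$layer_specs[1:13], function(s) s$shape[3L], integer(1))
  expect_identical(range(hw), c(14L, 224L))
  expect_identical(range(ch), c(64L, 512L))
  # inference requires supplied weights, never an implicit fetch
  img <- array(0.5, dim = c(224L, 224L, 3L))
  expect_error(extract_layer_activations(preprocess_image(img, b), b),
               "weights")
})

test_that("fixture backend is seed-deterministic and shape-consistent", {
  fb <- fixture_backend(42)
  img <- array(runif(32 * 32 * 3), dim = c(32L, 32L, 3L))
  a1 <- extract_layer_activations(img, fb)
  a2 <- extract_layer_activations(img, fixture_backend(42))
  expect_identical(a1, a2)
  expect_false(identical(
    extract_layer_activations(img, fixture_backend(43)), a1))
  # vector lengths equal the declared shape products; all post-ReLU
  expect_identical(lengths(a1), setNames(as.integer(layer_lengths(fb)),
                                         names(layer_lengths(fb))))
  expect_true(all(vapply(a1, min, numeric(1)) >= 0))
  kinds <- vapply(fb$layer_specs, `[[`, character(1), "kind")
  expect_identical(kinds, c(rep("convolution", 3L), "fully_connected"))
})

test_that("an all-zero image yields all-zero activations (zero biases)", {
  fb <- fixture_backend(1)
  z <- extract_layer_activations(array(0, dim = c(32L, 32L, 3L)), fb)
  expect_true(all(unlist(z) == 0))
})

test_that("unknown layer ids are rejected, requested subsets honoured", {
  fb <- fixture_backend(1)
  img <- array(runif(32 * 32 * 3), dim = c(32L, 32L, 3L))
  expect_error(extract_layer_activations(img, fb, layers = "conv9"),
               "unknown layer")
  sub <- extract_layer_activations(img, fb, layers = c("conv2", "fc1"))
  expect_identical(names(sub), c("conv2", "fc1"))
})

test_that("conv engine matches brute-force convolution", {
  set.seed(11)
  x <- array(rnorm(6 * 5 * 2), dim = c(6L, 5L, 2L))
  W <- array(rnorm(3 * 3 * 2 * 4), dim = c(3L, 3L, 2L, 4L))
  b <- rnorm(4)
  got <- sparsebeauty:::conv3x3(
    x, sparsebeauty:::reshape_conv_weights(W, 2L, 4L), b)
  # independent oracle: direct quintuple loop over the definition
  xp <- array(0, dim = c(8L, 7L, 2L))
  xp[2:7, 2:6, ] <- x
  want <- array(NA_real_, dim = c(6L, 5L, 4L))
  for (oc in 1:4) {
    for (i in 1:6) {
      for (j in 1:5) {
        acc <- b[oc]
        for (ic in 1:2) {
          for (di in 1:3) {
            for (dj in 1:3) {
              acc <- acc + xp[i + di - 1L, j + dj - 1L, ic] * W[di, dj, ic, oc]
            }
          }
        }
        want[i, j, oc] <- acc
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  # max pooling halves each spatial dimension, keeping block maxima
  p <- sparsebeauty:::maxpool2(got)
  expect_identical(dim(p), c(3L, 2L, 4L))
  expect_equal(p[1, 1, 2], max(got[1:2, 1:2, 2]))
})

test_that("preprocessing resizes, normalizes channels, flags bad input", {
  fb <- fixture_backend(1)
  big <- array(runif(64 * 48 * 3), dim = c(64L, 48L, 3L))
  out <- preprocess_image(big, fb)
  expect_identical(dim(out), c(32L, 32L, 3L))
  # identity resize leaves a matching image untouched (fixture
  # normalization is the identity)
  exact <- array(runif(32 * 32 * 3), dim = c(32L, 32L, 3L))
  expect_identical(preprocess_image(exact, fb), exact)
  # deterministic resampling
  expect_identical(preprocess_image(big, fb), out)
  # grayscale replicates to three identical channels
  gray <- matrix(runif(40 * 40), 40L, 40L)
  expect_warning(g3 <- preprocess_image(gray, fb), "grayscale")
  expect_identical(g3[, , 1L], g3[, , 2L])
  expect_identical(g3[, , 1L], g3[, , 3L])
  # alpha channel is dropped
  rgba <- array(runif(32 * 32 * 4), dim = c(32L, 32L, 4L))
  expect_warning(a3 <- preprocess_image(rgba, fb), "alpha")
  expect_identical(dim(a3), c(32L, 32L, 3L))
  expect_error(preprocess_image("no/such/file.png", fb), "not found")
  # a decodable file round-trips through the same path
  tmp <- tempfile(fileext = ".png")
  png::writePNG(array(runif(10 * 10 * 3), dim = c(10L, 10L, 3L)), tmp)
  expect_identical(dim(preprocess_image(tmp, fb)), c(32L, 32L, 3L))
})
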