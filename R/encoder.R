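#' Convolutional encoder backends
#'
#' An encoder backend turns a preprocessed image into per-layer post-ReLU
#' activation vectors. Two backends are provided: a VGG16-architecture
#' adapter (15 measured layers: 13 convolution + 2 fully connected) whose
#' pretrained weights the user supplies from a local file, and a small
#' seeded fixture network whose weights are fully determined by a seed,
#' so tests and simulations need no download. Both run through the same
#' forward engine (3x3 zero-padded convolution, 2x2 max pooling, fully
#' connected layers, ReLU); inference is deterministic — there is no
#' dropout or other training-time stochasticity.
#'
#' @name encoder-backends
NULL

layer_spec <- function(layer_id, kind, shape) {
  stopifnot(kind %in% c("convolution", "fully_connected"))
  list(layer_id = layer_id, kind = kind, shape = as.integer(shape))
}

# Number of entries in the flattened activation vector of one layer.
layer_length <- function(spec) prod(spec$shape)

#' Flattened activation-vector lengths of a backend
#'
#' @param backend an encoder backend.
#' @return named integer vector, one entry per measured layer.
#' @export
layer_lengths <- function(backend) {
  stopifnot(inherits(backend, "encoder_backend"))
  out <- vapply(backend$layer_specs, layer_length, numeric(1))
  names(out) <- vapply(backend$layer_specs, `[[`, character(1), "layer_id")
  out
}

new_encoder_backend <- function(name, input_size, layer_specs, arch,
                                normalization) {
  structure(
    list(name = name, input_size = as.integer(input_size),
         layer_specs = layer_specs, arch = arch,
         normalization = normalization),
    class = "encoder_backend"
  )
}

#' @export
print.encoder_backend <- function(x, ...) {
  cat("<encoder_backend>", x$name, "\n")
  cat("  input:", paste(x$input_size, collapse = "x"), "x3\n")
  for (s in x$layer_specs) {
    cat(sprintf("  %-10s %-16s %s\n", s$layer_id, s$kind,
                paste(s$shape, collapse = "x")))
  }
  invisible(x)
}

#' VGG16-architecture encoder adapter
#'
#' Builds the 15-layer measurement plan of the VGG16 architecture at
#' 224x224 input: 13 convolution layers (`conv1_1` ... `conv5_3`, feature
#' maps from 224x224x64 down to 14x14x512, activations taken after ReLU
#' and before pooling) and 2 fully connected layers (`fc1`, `fc2`, 4096
#' units each). Weights are never fetched implicitly: pass the path of a
#' local `.rds` file holding a named list with, per convolution layer, a
#' `(3, 3, in, out)` array `W` and length-`out` vector `b`, and per FC
#' layer an `(in, out)` matrix `W` and vector `b`. Without weights the
#' backend still exposes the full layer-shape plan (enough for
#' structural work); calling [extract_layer_activations()] then errors.
#'
#' @param weights optional path to an `.rds` weight file as described.
#' @return an `encoder_backend`.
#' @export
vgg16_backend <- function(weights = NULL) {
  blocks <- rep(1:5, times = c(2L, 2L, 3L, 3L, 3L))
  within <- sequence(c(2L, 2L, 3L, 3L, 3L))
  conv_ids <- paste0("conv", blocks, "_", within)
  channels <- c(64L, 128L, 256L, 512L, 512L)[blocks]
  sizes <- c(224L, 112L, 56L, 28L, 14L)[blocks]
  # pooling after the last convolution of each block
  pool_after <- c("conv1_2", "conv2_2", "conv3_3", "conv4_3", "conv5_3")

  specs <- vector("list", 15L)
  arch <- list()
  in_ch <- 3L
  for (k in seq_along(conv_ids)) {
    id <- conv_ids[k]
    specs[[k]] <- layer_spec(id, "convolution", c(sizes[k], sizes[k], channels[k]))
    arch[[length(arch) + 1L]] <- list(type = "conv", id = id,
                                      in_ch = in_ch, out_ch = channels[k])
    in_ch <- channels[k]
    if (id %in% pool_after) arch[[length(arch) + 1L]] <- list(type = "pool")
  }
  specs[[14L]] <- layer_spec("fc1", "fully_connected", 4096L)
  specs[[15L]] <- layer_spec("fc2", "fully_connected", 4096L)
  arch[[length(arch) + 1L]] <- list(type = "fc", id = "fc1",
                                    in_n = 7L * 7L * 512L, out_n = 4096L)
  arch[[length(arch) + 1L]] <- list(type = "fc", id = "fc2",
                                    in_n = 4096L, out_n = 4096L)

  backend <- new_encoder_backend(
    name = "vgg16_imagenet", input_size = c(224L, 224L),
    layer_specs = specs, arch = arch,
    # ImageNet per-channel normalization of the pretrained weight family
    normalization = list(mean = c(0.485, 0.456, 0.406),
                         sd = c(0.229, 0.224, 0.225))
  )
  if (!is.null(weights)) {
    backend$arch <- attach_weights(backend$arch, readRDS(weights))
    backend$weights_source <- weights
  }
  backend
}

attach_weights <- function(arch, wl) {
  for (k in seq_along(arch)) {
    step <- arch[[k]]
    if (step$type == "pool") next
    if (!step$id %in% names(wl)) {
      stop("weight file is missing layer ", step$id, call. = FALSE)
    }
    w <- wl[[step$id]]
    if (step$type == "conv") {
      arch[[k]]$W <- reshape_conv_weights(w$W, step$in_ch, step$out_ch)
    } else {
      stopifnot(identical(dim(w$W), c(step$in_n, step$out_n)))
      arch[[k]]$W <- w$W
    }
    arch[[k]]$b <- as.numeric(w$b)
  }
  arch
}

# (3, 3, in, out) kernel array (row offset, column offset, channel, unit)
# -> (9*in) x out matrix whose row order matches the im2col patch layout
# (row offset fastest, then column offset, then input channel).
reshape_conv_weights <- function(W, in_ch, out_ch) {
  stopifnot(identical(dim(W), c(3L, 3L, in_ch, out_ch)))
  matrix(W, nrow = 9L * in_ch, ncol = out_ch)
}

#' Seeded fixture encoder backend
#'
#' A small convolutional network (32x32x3 input; three 3x3 convolution
#' layers of 16, 32 and 64 channels, each followed by 2x2 max pooling,
#' then one 64-unit fully connected layer) with He-scaled Gaussian
#' weights and zero biases drawn from `seed`. The same seed yields
#' bit-identical weights and therefore bit-identical activations; it
#' stands in for the pretrained encoder wherever a download-free,
#' fully reproducible backend is needed.
#'
#' @param seed integer seed fully determining the weights.
#' @return an `encoder_backend` with loaded weights.
#' @export
fixture_backend <- function(seed = 1L) {
  sizes <- c(32L, 16L, 8L)
  channels <- c(16L, 32L, 64L)
  specs <- list(
    layer_spec("conv1", "convolution", c(32L, 32L, 16L)),
    layer_spec("conv2", "convolution", c(16L, 16L, 32L)),
    layer_spec("conv3", "convolution", c(8L, 8L, 64L)),
    layer_spec("fc1", "fully_connected", 64L)
  )
  arch <- with_seed(derive_seed(seed, 101L), {
    a <- list()
    in_ch <- 3L
    for (k in 1:3) {
      fan_in <- 9L * in_ch
      W <- matrix(rnorm(fan_in * channels[k], sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = channels[k])
      a[[length(a) + 1L]] <- list(type = "conv", id = paste0("conv", k),
                                  in_ch = in_ch, out_ch = channels[k],
                                  W = W, b = numeric(channels[k]))
      a[[length(a) + 1L]] <- list(type = "pool")
      in_ch <- channels[k]
    }
    in_n <- 4L * 4L * 64L
    a[[length(a) + 1L]] <- list(type = "fc", id = "fc1", in_n = in_n,
                                out_n = 64L,
                                W = matrix(rnorm(in_n * 64L, sd = sqrt(2 / in_n)),
                                           nrow = in_n, ncol = 64L),
                                b = numeric(64L))
    a
  })
  b <- new_encoder_backend(
    name = "fixture", input_size = c(32L, 32L),
    layer_specs = specs, arch = arch,
    normalization = list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  )
  b$seed <- as.integer(seed)
  b
}

#' Preprocess an image for an encoder backend
#'
#' Decodes PNG/JPEG (or accepts an `H x W x channels` array in `[0, 1]`),
#' converts grayscale to RGB by channel replication and drops an alpha
#' channel (with a warning in both cases), resizes to the backend's
#' input size by bilinear interpolation without preserving aspect ratio,
#' and applies the backend's per-channel normalization.
#'
#' @param image file path of a PNG/JPEG image, or a numeric array
#'   (`H x W`, `H x W x 1/3/4`) with values in `[0, 1]`.
#' @param backend an `encoder_backend`.
#' @return numeric `H x W x 3` array matching `backend$input_size`.
#' @export
preprocess_image <- function(image, backend) {
  stopifnot(inherits(backend, "encoder_backend"))
  if (is.character(image)) {
    if (!file.exists(image)) {
      stop("image file not found: ", image, call. = FALSE)
    }
    img <- tryCatch(EBImage::imageData(EBImage::readImage(image)),
                    error = function(e) {
                      stop("cannot decode image file ", image, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    # EBImage stores (x = width, y = height[, channel]); put H first
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
  } else if (is.numeric(image)) {
    img <- image
  } else {
    stop("image must be a file path or a numeric array", call. = FALSE)
  }
  if (length(dim(img) %||% integer()) == 0L || any(dim(img)[1:2] == 0L)) {
    stop("zero-size image", call. = FALSE)
  }
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  nc <- dim(img)[3L]
  if (nc == 4L) {
    warning("dropping alpha channel")
    img <- img[, , 1:3, drop = FALSE]
  } else if (nc == 1L) {
    warning("grayscale input: replicating channel to RGB")
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  } else if (nc == 2L) {
    warning("gray+alpha input: replicating gray channel, dropping alpha")
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  } else if (nc != 3L) {
    stop("unsupported channel count: ", nc, call. = FALSE)
  }
  h <- backend$input_size[1L]; w <- backend$input_size[2L]
  if (!identical(dim(img)[1:2], c(h, w))) {
    # EBImage resize is bilinear; it expects (x, y, c)
    r <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = w, h = h)
    img <- aperm(EBImage::imageData(r), c(2, 1, 3))
  }
  norm <- backend$normalization
  for (c in 1:3) img[, , c] <- (img[, , c] - norm$mean[c]) / norm$sd[c]
  img
}

#' Extract post-ReLU layer activations
#'
#' Runs the backend's forward pass over a preprocessed image and returns
#' the flattened post-ReLU activation vector of each requested layer.
#' Convolution-layer activations are taken after ReLU and before the
#' block's pooling step. Every returned value is non-negative and the
#' vector length equals the product of the declared layer shape.
#'
#' @param image preprocessed `H x W x 3` array (see [preprocess_image()]).
#' @param backend an `encoder_backend` with weights loaded.
#' @param layers character vector of layer ids to export; default all
#'   measured layers of the backend.
#' @return named list of numeric vectors, one per requested layer.
#' @export
extract_layer_activations <- function(image, backend, layers = NULL) {
  stopifnot(inherits(backend, "encoder_backend"))
  ids <- vapply(backend$layer_specs, `[[`, character(1), "layer_id")
  layers <- layers %||% ids
  unknown <- setdiff(layers, ids)
  if (length(unknown)) {
    stop("unknown layer id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_weights <- all(vapply(backend$arch, function(s) {
    s$type == "pool" || !is.null(s$W)
  }, logical(1)))
  if (!has_weights) {
    stop("backend '", backend$name, "' has no weights loaded; ",
         "supply a weight file to run inference", call. = FALSE)
  }
  stopifnot(is.numeric(image),
            identical(dim(image)[1:2], backend$input_size),
            dim(image)[3L] == 3L)

  out <- list()
  x <- image
  for (step in backend$arch) {
    if (step$type == "pool") {
      x <- maxpool2(x)
    } else if (step$type == "conv") {
      x <- relu(conv3x3(x, step$W, step$b))
      if (step$id %in% layers) out[[step$id]] <- as.vector(x)
    } else {
      x <- relu(as.vector(as.vector(x) %*% step$W) + step$b)
      if (step$id %in% layers) out[[step$id]] <- x
    }
    if (length(out) == length(layers)) break
  }
  out[layers]
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# 3x3 convolution, stride 1, zero padding 1, via im2col + matmul.
# W is (9*Cin) x Cout with rows ordered (di, dj, channel), di fastest.
conv3x3 <- function(x, W, b) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  xp <- array(0, dim = c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, nrow = h * w, ncol = 9L * cin)
  k <- 1L
  for (cc in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        cols[, k] <- xp[di + seq_len(h), dj + seq_len(w), cc]
        k <- k + 1L
      }
    }
  }
  out <- cols %*% W
  out <- sweep(out, 2L, b, `+`)
  array(out, dim = c(h, w, ncol(W)))
}

# 2x2 max pooling, stride 2; a trailing odd row/column is dropped.
maxpool2 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  io <- seq(1L, h - 1L, by = 2L); jo <- seq(1L, w - 1L, by = 2L)
  pmax(x[io, jo, , drop = FALSE], x[io + 1L, jo, , drop = FALSE],
       x[io, jo + 1L, , drop = FALSE], x[io + 1L, jo + 1L, , drop = FALSE])
}
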