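#' Classifier architecture specification
#'
#' The per-subject classifier is a two-block squeeze-and-excitation CNN:
#' each block is convolution (kernel x kernel, stride 1, `same` padding) ->
#' batch norm -> LeakyReLU -> max pool -> dropout -> SE gating, and the
#' post-SE activations `h1` and `h2` are the feature maps the style and
#' content losses consume. A dense head maps the flattened second block to
#' `K` class logits.
#'
#' @param channels,n_freqs,n_times Input image dimensions: EEG electrodes
#'   (image channels), scalogram frequency rows, and time columns.
#' @param K Number of classes (4 for IV-2a-style data, 2 for IV-2b-style).
#' @param conv_channels Output channels of the two conv blocks.
#' @param kernel Convolution kernel size (square).
#' @param pool Max-pool size per block.
#' @param dropout Dropout rate.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(channels, n_freqs, n_times, K = 4L,
                            conv_channels = c(32L, 64L), kernel = 5L,
                            pool = 2L, dropout = 0.25, se_reduction = 8L,
                            leaky_slope = 0.2) {
  stopifnot(length(conv_channels) == 2L)
  check_number(dropout, "dropout", lower = 0, upper = 1, strict_upper = TRUE)
  structure(list(channels = as.integer(channels),
                 n_freqs = as.integer(n_freqs),
                 n_times = as.integer(n_times), K = as.integer(K),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dropout = dropout, se_reduction = as.integer(se_reduction),
                 leaky_slope = leaky_slope),
            class = "classifier_spec")
}

#' Build a classifier with freshly initialized parameters
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed controlling initialization.
#' @return An `ssstn_classifier` object.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  pad <- (spec$kernel - 1L) %/% 2L
  H1 <- spec$n_freqs %/% spec$pool
  W1 <- spec$n_times %/% spec$pool
  H2 <- H1 %/% spec$pool
  W2 <- W1 %/% spec$pool
  if (H2 < 1L || W2 < 1L) abort_arg("input image too small for two pools.")
  layers <- with_seed(derive_seed(seed, "classifier"), {
    l <- list(
      layer_conv2d(spec$channels, spec$conv_channels[1L], spec$kernel,
                   1L, pad),
      layer_batchnorm(spec$conv_channels[1L]),
      layer_leakyrelu(spec$leaky_slope),
      layer_maxpool(spec$pool),
      layer_dropout(spec$dropout),
      layer_se(spec$conv_channels[1L], spec$se_reduction, spec$leaky_slope),
      layer_conv2d(spec$conv_channels[1L], spec$conv_channels[2L],
                   spec$kernel, 1L, pad),
      layer_batchnorm(spec$conv_channels[2L]),
      layer_leakyrelu(spec$leaky_slope),
      layer_maxpool(spec$pool),
      layer_dropout(spec$dropout),
      layer_se(spec$conv_channels[2L], spec$se_reduction, spec$leaky_slope),
      layer_dense(H2 * W2 * spec$conv_channels[2L], spec$K)
    )
    l[[6L]]$tap <- "h1"
    l[[12L]]$tap <- "h2"
    l
  })
  structure(list(spec = spec, layers = layers), class = "ssstn_classifier")
}

# Coerce user-facing image input to the internal (F, T, C, N) layout.
# Accepts: a single C x F x T array, an N x C x F x T array, or a
# scalogram_set.
as_image_batch <- function(x, spec) {
  if (inherits(x, "scalogram_set")) x <- x$images
  d <- dim(x)
  if (is.null(d)) abort_arg("images must be an array.")
  if (length(d) == 3L) {
    x <- array(x, dim = c(d, 1L))
    x <- aperm(x, c(2L, 3L, 1L, 4L))
  } else if (length(d) == 4L) {
    x <- aperm(x, c(3L, 4L, 2L, 1L))
  } else {
    abort_arg("images must have 3 (C,F,T) or 4 (N,C,F,T) dimensions.")
  }
  d <- dim(x)
  dims_exp <- c(spec$n_freqs, spec$n_times, spec$channels)
  axis_names <- c("frequencies", "time points", "channels")
  for (ax in 1:3) {
    if (d[ax] != dims_exp[ax]) {
      rlang::abort(sprintf(
        "image %s axis has size %d but the model expects %d",
        axis_names[ax], d[ax], dims_exp[ax]), class = "ssstn_shape_error")
    }
  }
  x
}

# Feature tap (H, W, Cf, N) -> feature-channels x M x N array.
tap_to_feature_maps <- function(tap) {
  d <- dim(tap)
  M <- d[1L] * d[2L]
  out <- array(0, dim = c(d[3L], M, d[4L]))
  for (n in seq_len(d[4L])) {
    out[, , n] <- t(matrix(tap[, , , n], M, d[3L]))
  }
  out
}

#' Forward pass of the classifier
#'
#' @param model An `ssstn_classifier`.
#' @param images A single `C x F x T` image, an `N x C x F x T` batch, or a
#'   `scalogram_set`.
#' @param training Logical: use batch statistics and active dropout
#'   (training mode) instead of deterministic evaluation mode.
#' @return A list with `features` (list `h1`, `h2` of
#'   feature-channels x locations x batch arrays, the post-SE activations)
#'   and `prediction` (list with `logits` and softmax `probabilities`, both
#'   `K x N`).
#' @export
classifier_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "ssstn_classifier"))
  x <- as_image_batch(images, model$spec)
  fwd <- net_forward(model$layers, x, training)
  probs <- apply(fwd$out, 2L, softmax_vec)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = model$spec$K)
  list(features = list(h1 = tap_to_feature_maps(fwd$taps$h1),
                       h2 = tap_to_feature_maps(fwd$taps$h2)),
       prediction = list(logits = fwd$out, probabilities = probs))
}

#' Generator architecture specification
#'
#' Encoder-decoder image-to-image network: three stride-2 convolutions
#' (batch norm, LeakyReLU, dropout after each) halve the spatial grid while
#' widening channels; three transposed convolutions mirror them back, with
#' a residual self-attention layer (learnable scale initialized at 0) after
#' the first and second, and a logistic output activation bounding the
#' image to `[0, 1]`. Output dimensions always equal input dimensions.
#'
#' @inheritParams classifier_spec
#' @param enc_channels Channels of the three encoder stages.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(channels, n_freqs, n_times,
                           enc_channels = c(32L, 64L, 128L), kernel = 4L,
                           dropout = 0.25, leaky_slope = 0.2) {
  stopifnot(length(enc_channels) == 3L)
  structure(list(channels = as.integer(channels),
                 n_freqs = as.integer(n_freqs),
                 n_times = as.integer(n_times),
                 enc_channels = as.integer(enc_channels),
                 kernel = as.integer(kernel), dropout = dropout,
                 leaky_slope = leaky_slope),
            class = "generator_spec")
}

conv_out_size <- function(n, kernel, stride, pad) {
  (n + 2L * pad - kernel) %/% stride + 1L
}

#' Build a generator with freshly initialized parameters
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed controlling initialization.
#' @return An `ssstn_generator` object.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- spec$kernel
  pad <- 1L
  shapes <- list(c(spec$n_freqs, spec$n_times))
  for (s in 1:3) {
    prev <- shapes[[s]]
    shapes[[s + 1L]] <- c(conv_out_size(prev[1L], k, 2L, pad),
                          conv_out_size(prev[2L], k, 2L, pad))
  }
  if (any(shapes[[4L]] < 1L)) abort_arg("input image too small for the encoder.")
  ec <- spec$enc_channels
  layers <- with_seed(derive_seed(seed, "generator"), list(
    layer_conv2d(spec$channels, ec[1L], k, 2L, pad),
    layer_batchnorm(ec[1L]),
    layer_leakyrelu(spec$leaky_slope),
    layer_dropout(spec$dropout),
    layer_conv2d(ec[1L], ec[2L], k, 2L, pad),
    layer_batchnorm(ec[2L]),
    layer_leakyrelu(spec$leaky_slope),
    layer_dropout(spec$dropout),
    layer_conv2d(ec[2L], ec[3L], k, 2L, pad),
    layer_batchnorm(ec[3L]),
    layer_leakyrelu(spec$leaky_slope),
    layer_dropout(spec$dropout),
    layer_tconv2d(ec[3L], ec[2L], k, 2L, pad, target = shapes[[3L]]),
    layer_attention(ec[2L]),
    layer_batchnorm(ec[2L]),
    layer_leakyrelu(spec$leaky_slope),
    layer_dropout(spec$dropout),
    layer_tconv2d(ec[2L], ec[1L], k, 2L, pad, target = shapes[[2L]]),
    layer_attention(ec[1L]),
    layer_batchnorm(ec[1L]),
    layer_leakyrelu(spec$leaky_slope),
    layer_dropout(spec$dropout),
    layer_tconv2d(ec[1L], spec$channels, k, 2L, pad, target = shapes[[1L]]),
    layer_sigmoid()
  ))
  structure(list(spec = spec, layers = layers), class = "ssstn_generator")
}

#' Forward pass of the generator
#'
#' @param model An `ssstn_generator`.
#' @param images A single `C x F x T` image, an `N x C x F x T` batch, or a
#'   `scalogram_set`.
#' @param training Logical; see [classifier_forward()].
#' @return An array of transformed images in the same layout as the input
#'   (`C x F x T` or `N x C x F x T`), with identical dimensions.
#' @export
generator_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "ssstn_generator"))
  single <- !inherits(images, "scalogram_set") && length(dim(images)) == 3L
  x <- as_image_batch(images, model$spec)
  fwd <- net_forward(model$layers, x, training)
  out <- aperm(fwd$out, c(4L, 3L, 1L, 2L))           # N, C, F, T
  if (single) array(out[1L, , , ], dim = dim(out)[-1L]) else out
}

#' Standalone squeeze-and-excitation gate
#'
#' Functional form of the SE module: squeeze (global average per feature
#' channel), bottleneck MLP with LeakyReLU then a logistic gate, and
#' channel-wise rescaling of the input.
#'
#' @param features Feature-channels x spatial-locations numeric matrix.
#' @param reduction Bottleneck reduction ratio.
#' @param params Optional list `W1, b1, W2, b2`; drawn from the current RNG
#'   stream when `NULL`.
#' @param identity_gate If TRUE, forces every gate to 1 (test hook: output
#'   equals input).
#' @return A matrix of the same shape as `features`.
#' @export
se_block <- function(features, reduction = 8L, params = NULL,
                     identity_gate = FALSE) {
  stopifnot(is.matrix(features))
  if (identity_gate) return(features)
  ch <- nrow(features)
  lay <- layer_se(ch, reduction)
  if (!is.null(params)) lay$params <- params
  x <- array(t(features), dim = c(ncol(features), 1L, ch, 1L))
  y <- se_forward(lay, x, training = FALSE)$out
  t(matrix(y, ncol(features), ch))
}

#' Standalone self-attention over spatial locations
#'
#' Query/key/value projections, spatial affinity via a normalized
#' exponential map, and residual addition scaled by `gamma` (0 gives the
#' identity map).
#'
#' @param features Feature-channels x spatial-locations numeric matrix.
#' @param params Optional list `Wq, Wk, Wv`; drawn from the current RNG
#'   stream when `NULL`.
#' @param gamma Residual scale (learned during training; initialized 0).
#' @param key_dim Dimension of the query/key projections.
#' @return A matrix of the same shape as `features`.
#' @export
self_attention <- function(features, params = NULL, gamma = 0,
                           key_dim = NULL) {
  stopifnot(is.matrix(features))
  ch <- nrow(features)
  lay <- layer_attention(ch, key_dim)
  if (!is.null(params)) lay$params[names(params)] <- params
  lay$params$gamma <- gamma
  x <- array(t(features), dim = c(ncol(features), 1L, ch, 1L))
  y <- attention_forward(lay, x, training = FALSE)$out
  t(matrix(y, ncol(features), ch))
}

#' Count trainable parameters of a model
#'
#' @param model An `ssstn_classifier` or `ssstn_generator`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(l$params, length, integer(1L)), 0L)
  }, numeric(1L)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec; loading verifies it against
#' `expected_spec` when supplied.
#'
#' @param model An `ssstn_classifier` or `ssstn_generator`.
#' @param path File path.
#' @param expected_spec Optional spec that the stored spec must equal.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("ssstn_classifier", "ssstn_generator")))
  saveRDS(model, path, version = 2L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expected_spec = NULL) {
  model <- readRDS(path)
  if (!inherits(model, c("ssstn_classifier", "ssstn_generator"))) {
    abort_arg(sprintf("`%s` is not a model checkpoint.", path))
  }
  if (!is.null(expected_spec) && !identical(model$spec, expected_spec)) {
    abort_arg("checkpoint architecture spec does not match `expected_spec`.")
  }
  model
}
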