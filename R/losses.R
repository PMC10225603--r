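# Loss functions of the style-transfer objective. Feature maps are
# feature-channels x M matrices (one layer, one sample), or
# feature-channels x M x N arrays for a batch; `FeatureMaps` lists hold one
# such entry per tapped layer (h1, h2).

EPS_LOG <- 1e-12

as_fm_array <- function(h) {
  if (is.matrix(h)) h <- array(h, dim = c(dim(h), 1L))
  stopifnot(length(dim(h)) == 3L)
  h
}

#' Cross-entropy classification loss
#'
#' `-sum_k y_k log p_k` with one-hot `y`; probabilities are clamped at
#' 1e-12 so the loss is never infinite.
#'
#' @param prediction A probability vector of length `K`, a `K x N` matrix
#'   of per-sample probabilities, or the `prediction` element returned by
#'   [classifier_forward()].
#' @param label Class index in `1..K` (vectorized over samples).
#' @param K Number of classes (inferred from `prediction` when missing).
#' @return Mean cross-entropy over the samples (a single non-negative
#'   number).
#' @export
classification_loss <- function(prediction, label, K = NULL) {
  p <- prediction
  if (is.list(p)) p <- p$probabilities
  if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  K <- K %||% nrow(p)
  if (nrow(p) != K) abort_arg("`prediction` has the wrong class count.")
  label <- vapply(label, check_label, integer(1L), K = K)
  if (length(label) != ncol(p)) {
    abort_arg("`label` length must match the number of predictions.")
  }
  picked <- p[cbind(label, seq_along(label))]
  mean(-log(pmax(picked, EPS_LOG)))
}

#' Gram matrix of a layer's feature maps
#'
#' `Gr[i, j] = sum_m h[i, m] h[j, m]`: inner products between vectorized
#' feature maps, with no normalization by the number of locations.
#' Symmetric and positive semi-definite by construction.
#'
#' @param h Feature-channels x locations numeric matrix.
#' @return Feature-channels x feature-channels matrix.
#' @export
gram <- function(h) {
  stopifnot(is.matrix(h), ncol(h) >= 1L)
  tcrossprod(h)
}

# KL(softmax(flatten(Gram(ht))) || softmax(flatten(Gram(hs)))) for one
# layer and one sample.
style_kl_one <- function(ht, hs) {
  p <- softmax_vec(as.numeric(gram(ht)))
  q <- softmax_vec(as.numeric(gram(hs)))
  sum(p * (log(pmax(p, EPS_LOG)) - log(pmax(q, EPS_LOG))))
}

#' Style loss: KL divergence between softmaxed Gram matrices
#'
#' For each paired sample and each tapped layer, both Gram matrices are
#' flattened, mapped through a softmax, and compared with
#' `KL(transferred || source)`; contributions are summed over layers and
#' over the N pairs (the direction of the divergence is fixed and the loss
#' is not symmetric in its arguments).
#'
#' @param h_transferred,h_source `FeatureMaps`: lists of per-layer
#'   feature-channels x M (x N) arrays, e.g. the `features` element of
#'   [classifier_forward()] applied to the transferred and source images.
#'   Samples are paired one-to-one.
#' @return Non-negative scalar.
#' @export
style_loss <- function(h_transferred, h_source) {
  stopifnot(length(h_transferred) == length(h_source))
  total <- 0
  for (l in seq_along(h_transferred)) {
    ht <- as_fm_array(h_transferred[[l]])
    hs <- as_fm_array(h_source[[l]])
    if (!all(dim(ht) == dim(hs))) {
      rlang::abort(sprintf("layer %d feature shapes differ between sides", l),
                   class = "ssstn_shape_error")
    }
    if (any(!is.finite(ht)) || any(!is.finite(hs))) {
      rlang::abort(sprintf("non-finite feature value in layer %d", l),
                   class = "ssstn_numeric_error")
    }
    d <- dim(ht)
    for (n in seq_len(d[3L])) {
      total <- total + style_kl_one(matrix(ht[, , n], d[1L], d[2L]),
                                    matrix(hs[, , n], d[1L], d[2L]))
    }
  }
  total
}

#' Content loss: cross-classifier feature distance
#'
#' Mean over the N samples of the sum over layers of the mean squared
#' element-wise difference between the target classifier's features on the
#' original target images and the source classifier's features on the
#' transferred images.
#'
#' @param h_target,h_transferred `FeatureMaps` as in [style_loss()], from
#'   the target classifier on `x_T` and the source classifier on the
#'   generated `x_S'` respectively.
#' @return Non-negative scalar.
#' @export
content_loss <- function(h_target, h_transferred) {
  stopifnot(length(h_target) == length(h_transferred))
  N <- NULL
  total <- 0
  for (l in seq_along(h_target)) {
    ht <- as_fm_array(h_target[[l]])
    hs <- as_fm_array(h_transferred[[l]])
    if (!all(dim(ht) == dim(hs))) {
      rlang::abort(sprintf("layer %d feature shapes differ between sides", l),
                   class = "ssstn_shape_error")
    }
    N <- N %||% dim(ht)[3L]
    per_el <- dim(ht)[1L] * dim(ht)[2L]
    total <- total + sum((ht - hs)^2) / per_el
  }
  total / N
}

#' Semantic loss: source-classifier cross-entropy on transferred images
#'
#' Cross-entropy of the source classifier's prediction on the generated
#' image against the target trial's ground-truth label — the term that
#' directly pushes the transferred image to be classified correctly.
#'
#' @param pred_transferred Prediction (probability vector/matrix or
#'   [classifier_forward()] prediction element) of the source classifier on
#'   the transferred images.
#' @param label_target Ground-truth target label(s).
#' @param K Number of classes.
#' @return Non-negative scalar.
#' @export
semantic_loss <- function(pred_transferred, label_target, K = NULL) {
  classification_loss(pred_transferred, label_target, K)
}

#' Loss weights of the combined objective
#'
#' @param alpha,beta_w,gamma Non-negative weights of the style, content and
#'   semantic terms. Defaults are the published operating point
#'   (0.1, 1, 1). `beta_w` is named to avoid a clash with the Morlet width
#'   parameter.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(alpha = 0.1, beta_w = 1, gamma = 1) {
  check_number(alpha, "alpha", lower = 0)
  check_number(beta_w, "beta_w", lower = 0)
  check_number(gamma, "gamma", lower = 0)
  structure(list(alpha = alpha, beta_w = beta_w, gamma = gamma),
            class = "loss_weights")
}

#' Combine the three loss components
#'
#' `total = alpha * style + beta_w * content + gamma * semantic`.
#'
#' @param style,content,semantic Finite component values.
#' @param weights A [loss_weights()].
#' @return A `loss_report`: list with the components, the weights and
#'   `total`.
#' @export
total_loss <- function(style, content, semantic, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  for (v in c(style, content, semantic)) {
    if (!is.finite(v)) abort_arg("loss components must be finite.")
  }
  structure(list(style = style, content = content, semantic = semantic,
                 weights = weights,
                 total = weights$alpha * style + weights$beta_w * content +
                   weights$gamma * semantic),
            class = "loss_report")
}

## ---- gradients (internal, used by the generator trainer) ----------------

# d style_kl_one / d ht for one layer/sample (q from the source side is a
# constant).
style_grad_one <- function(ht, q_soft) {
  g <- as.numeric(gram(ht))
  p <- softmax_vec(g)
  u <- log(pmax(p, EPS_LOG)) - log(pmax(q_soft, EPS_LOG))
  dg <- p * (u - sum(p * u))
  dG <- matrix(dg, nrow(ht), nrow(ht))
  (dG + t(dG)) %*% ht
}

# d content / d h_transferred for one layer (batch array), given N and the
# per-layer element count normalization.
content_grad_layer <- function(ht_target, ht_transferred, N) {
  per_el <- dim(ht_target)[1L] * dim(ht_target)[2L]
  2 * (ht_transferred - ht_target) / per_el / N
}

# d mean-CE / d logits for softmax probabilities p (K x N) and labels.
ce_logit_grad <- function(p, labels) {
  N <- ncol(p)
  y <- matrix(0, nrow(p), N)
  y[cbind(labels, seq_len(N))] <- 1
  (p - y) / N
}
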