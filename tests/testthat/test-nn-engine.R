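# The backpropagation engine: every layer's analytic gradients against
# central finite differences, plus a conv-vs-naive-loop oracle.

check_layer_grads <- function(make_layer, dimx, training = TRUE,
                              tol = 1e-6) {
  lay <- make_layer()
  x <- array(stats::rnorm(prod(dimx)), dim = dimx)
  fwd <- ssstn:::layer_forward(lay, x, training)
  # L = sum(out^2)/2 so dL/dout = out
  bwd <- ssstn:::layer_backward(lay, fwd$out, fwd$cache)
  f_x <- function(xv) {
    sum(ssstn:::layer_forward(lay, array(xv, dim = dimx), training)$out^2) / 2
  }
  gx <- num_grad(f_x, as.numeric(x))
  expect_lt(max(abs(gx - as.numeric(bwd$dx))), tol)
  for (nm in names(lay$params)) {
    p0 <- lay$params[[nm]]
    f_p <- function(pv) {
      l2 <- lay
      l2$params[[nm]] <- reshape_like(pv, p0)
      sum(ssstn:::layer_forward(l2, x, training)$out^2) / 2
    }
    gp <- num_grad(f_p, as.numeric(p0))
    expect_lt(max(abs(gp - as.numeric(bwd$grads[[nm]]))), tol)
  }
}

test_that("every layer's backward pass matches finite differences", {
  set.seed(21)
  check_layer_grads(function() ssstn:::layer_conv2d(2L, 3L, 3L, 1L, 1L),
                    c(5L, 6L, 2L, 2L))
  check_layer_grads(function() ssstn:::layer_conv2d(2L, 4L, 3L, 2L, 1L),
                    c(5L, 6L, 2L, 2L))
  check_layer_grads(function() ssstn:::layer_tconv2d(3L, 2L, 4L, 2L, 1L,
                                                     target = c(9L, 11L)),
                    c(5L, 6L, 3L, 2L))
  check_layer_grads(function() ssstn:::layer_batchnorm(3L),
                    c(4L, 5L, 3L, 2L), training = TRUE)
  check_layer_grads(function() ssstn:::layer_batchnorm(3L),
                    c(4L, 5L, 3L, 2L), training = FALSE)
  check_layer_grads(function() ssstn:::layer_leakyrelu(0.2),
                    c(4L, 5L, 3L, 2L))
  check_layer_grads(function() ssstn:::layer_maxpool(2L), c(5L, 6L, 3L, 2L))
  check_layer_grads(function() ssstn:::layer_se(4L, 2L), c(3L, 4L, 4L, 2L))
  check_layer_grads(function() {
    l <- ssstn:::layer_attention(4L)
    l$params$gamma <- 0.7
    l
  }, c(2L, 3L, 4L, 2L))
  check_layer_grads(function() ssstn:::layer_dense(24L, 3L),
                    c(2L, 2L, 6L, 2L))
  check_layer_grads(function() ssstn:::layer_sigmoid(), c(3L, 4L, 2L, 2L))
})

test_that("im2col convolution equals a naive quadruple loop", {
  set.seed(22)
  lay <- ssstn:::layer_conv2d(2L, 3L, 3L, 1L, 1L)
  x <- array(stats::rnorm(7 * 8 * 2 * 2), dim = c(7L, 8L, 2L, 2L))
  out <- ssstn:::layer_forward(lay, x, FALSE)$out
  # naive direct convolution with zero padding
  W <- lay$params$W                       # out_ch x (kh, kw, in_ch)
  ref <- array(0, dim = dim(out))
  xp <- array(0, dim = c(9L, 10L, 2L, 2L))
  xp[2:8, 2:9, , ] <- x
  for (n in 1:2) for (oc in 1:3) for (oh in 1:7) for (ow in 1:8) {
    acc <- lay$params$b[oc]
    r <- 0L
    for (ic in 1:2) for (kw in 1:3) for (kh in 1:3) {
      r <- r + 1L
      # weight row order: kh fastest, then kw, then ic
      w_r <- (ic - 1L) * 9L + (kw - 1L) * 3L + kh
      acc <- acc + W[oc, w_r] * xp[oh + kh - 1L, ow + kw - 1L, ic, n]
    }
    ref[oh, ow, oc, n] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  # <conv(x), y> == <x, tconv(y)> when the two share one kernel
  set.seed(23)
  conv <- ssstn:::layer_conv2d(2L, 3L, 4L, 2L, 1L)
  tcon <- ssstn:::layer_tconv2d(3L, 2L, 4L, 2L, 1L)
  tcon$params$W <- conv$params$W        # shared kernel, adjoint direction
  tcon$params$b <- numeric(2L)
  conv$params$b <- numeric(3L)
  x <- array(stats::rnorm(6 * 8 * 2), dim = c(6L, 8L, 2L, 1L))
  cx <- ssstn:::layer_forward(conv, x, FALSE)$out
  y <- array(stats::rnorm(length(cx)), dim = dim(cx))
  ty <- ssstn:::layer_forward(tcon, y, FALSE)$out
  expect_equal(sum(cx * y), sum(x * ty), tolerance = 1e-10)
})

test_that("maxpool takes block maxima and routes gradients to them", {
  x <- array(0, dim = c(2L, 2L, 1L, 1L))
  x[, , 1L, 1L] <- matrix(c(1, 4, 3, 2), 2L)
  lay <- ssstn:::layer_maxpool(2L)
  fwd <- ssstn:::layer_forward(lay, x, FALSE)
  expect_equal(as.numeric(fwd$out), 4)
  bwd <- ssstn:::layer_backward(lay, fwd$out * 0 + 1, fwd$cache)
  expect_equal(as.numeric(bwd$dx[, , 1L, 1L]), c(0, 1, 0, 0))
})

test_that("adam reduces a simple quadratic deterministically", {
  lay <- ssstn:::layer_dense(4L, 1L)
  lay$params$W <- matrix(c(3, -2, 1, 4), 1L)
  lay$params$b <- 5
  layers <- list(lay)
  st <- ssstn:::adam_init(layers)
  for (t in 1:300) {
    grads <- list(list(W = 2 * layers[[1L]]$params$W,
                       b = 2 * layers[[1L]]$params$b))
    upd <- ssstn:::adam_step(layers, grads, st, lr = 0.05, t = t)
    layers <- upd$layers
    st <- upd$state
  }
  expect_lt(max(abs(unlist(layers[[1L]]$params))), 0.05)
})
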