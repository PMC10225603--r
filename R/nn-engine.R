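# Minimal dense/conv neural-network engine with explicit backpropagation.
#
# Tensors are numeric arrays with dims (H, W, C, N): spatial rows
# (frequencies), spatial cols (time), feature channels, batch. All layers
# implement:
#   layer_forward(layer, x, training) -> list(out, cache)
#   layer_backward(layer, dout, cache) -> list(dx, grads)
# with `grads` mirroring layer$params. Convolutions are im2col + BLAS
# matmul; transposed convolutions are the exact adjoint (col2im) of a
# convolution. Optimization is Adam.

## ---- parameter initialization -------------------------------------------

he_init <- function(n, fan_in, slope = 0.2) {
  sd <- sqrt(2 / ((1 + slope^2) * fan_in))
  stats::rnorm(n, sd = sd)
}

## ---- im2col index machinery ---------------------------------------------

# Shape-keyed memo for gather indices: convolution shapes repeat every
# step, so the index vectors are computed once per (shape, batch) and
# shared thereafter (R copy-on-write keeps this cheap).
.idx_cache <- new.env(parent = emptyenv())

# Precompute linear gather indices into a zero-padded (Hp, Wp, C) block for
# every kernel element (rows) and output position (cols). Row order:
# kh fastest, then kw, then c — the same order the weight matrix uses.
im2col_idx <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  OH <- (Hp - kh) %/% stride + 1L
  OW <- (Wp - kw) %/% stride + 1L
  g <- expand.grid(kh = seq_len(kh), kw = seq_len(kw), c = seq_len(C))
  oh <- rep(seq.int(0L, OH - 1L) * stride, times = OW)       # per output col
  ow <- rep(seq.int(0L, OW - 1L) * stride, each = OH)
  # idx[r, p] = linear index of (g$kh[r] + oh[p], g$kw[r] + ow[p], g$c[r])
  hh <- outer(g$kh, oh, "+")                                  # K_ x P
  ww <- outer(g$kw, ow, "+")
  idx <- hh + Hp * (ww - 1L) + (Hp * Wp) * (g$c - 1L)
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp, C = C,
              K_ = nrow(idx), P = ncol(idx), key = key)
  .idx_cache[[key]] <- out
  out
}

# Full batch-expanded gather index for a map, memoized per batch size.
batch_idx <- function(map, N) {
  key <- paste(map$key, "N", N, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  block <- map$Hp * map$Wp * map$C
  full <- rep.int(as.numeric(map$idx), N) +
    rep(block * (seq_len(N) - 1), each = map$K_ * map$P)
  if (max(full) < .Machine$integer.max) full <- as.integer(full)
  .idx_cache[[key]] <- full
  full
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  out[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ] <- x
  out
}

unpad_hw <- function(x, pad, H, W) {
  if (pad == 0L) return(x)
  x[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

# Gather x (Hp, Wp, C, N) into a K_ x (P * N) matrix.
im2col <- function(xp, map) {
  N <- dim(xp)[4L]
  full <- batch_idx(map, N)
  matrix(xp[full], nrow = map$K_)
}

# Cached sparse scatter operator: col2im is the exact adjoint of the
# im2col gather, realized as one sparse matrix-vector product.
col2im_op <- function(map, N) {
  key <- paste(map$key, "S", N, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  full <- batch_idx(map, N)
  S <- Matrix::sparseMatrix(i = full, j = seq_along(full), x = 1,
                            dims = c(map$Hp * map$Wp * map$C * N,
                                     length(full)))
  .idx_cache[[key]] <- S
  S
}

# Scatter-add cols (K_ x (P * N)) back into a padded (Hp, Wp, C, N) array.
col2im <- function(cols, map, N) {
  S <- col2im_op(map, N)
  dim(cols) <- NULL
  array((S %*% cols)@x, dim = c(map$Hp, map$Wp, map$C, N))
}

## ---- layers --------------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, kernel = 5L, stride = 1L,
                         pad = 2L) {
  K_ <- kernel * kernel * in_ch
  list(type = "conv2d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, pad = pad,
       params = list(W = matrix(he_init(out_ch * K_, K_), out_ch, K_),
                     b = numeric(out_ch)))
}

conv2d_forward <- function(layer, x, training) {
  d <- dim(x)
  map <- im2col_idx(d[1L], d[2L], d[3L], layer$kernel, layer$kernel,
                    layer$stride, layer$pad)
  xp <- pad_hw(x, layer$pad)
  cols <- im2col(xp, map)
  out <- layer$params$W %*% cols + layer$params$b     # out_ch x (P*N)
  out <- array(out, dim = c(layer$out_ch, map$OH, map$OW, d[4L]))
  out <- aperm(out, c(2L, 3L, 1L, 4L))
  list(out = out, cache = list(cols = cols, map = map, in_dim = d))
}

conv2d_backward <- function(layer, dout, cache) {
  d <- cache$in_dim
  map <- cache$map
  dm <- aperm(dout, c(3L, 1L, 2L, 4L))                 # out_ch, OH, OW, N
  dm <- matrix(dm, nrow = layer$out_ch)
  dW <- tcrossprod(dm, cache$cols)
  db <- rowSums(dm)
  dcols <- crossprod(layer$params$W, dm)               # K_ x (P*N)
  dxp <- col2im(dcols, map, d[4L])
  dx <- unpad_hw(dxp, layer$pad, d[1L], d[2L])
  list(dx = dx, grads = list(W = dW, b = db))
}

# Transposed convolution: the adjoint of a stride-s convolution from the
# output grid back to the input grid. Output spatial size:
# (H - 1) * stride + kernel - 2 * pad, then cropped/padded to `target`
# (trailing edge) when given.
layer_tconv2d <- function(in_ch, out_ch, kernel = 4L, stride = 2L,
                          pad = 1L, target = NULL) {
  K_ <- kernel * kernel * out_ch
  list(type = "tconv2d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, pad = pad, target = target,
       params = list(W = matrix(he_init(in_ch * K_, K_), in_ch, K_),
                     b = numeric(out_ch)))
}

tconv2d_forward <- function(layer, x, training) {
  d <- dim(x)                                           # H, W, in_ch, N
  OH <- (d[1L] - 1L) * layer$stride + layer$kernel - 2L * layer$pad
  OW <- (d[2L] - 1L) * layer$stride + layer$kernel - 2L * layer$pad
  map <- im2col_idx(OH, OW, layer$out_ch, layer$kernel, layer$kernel,
                    layer$stride, layer$pad)
  stopifnot(map$OH == d[1L], map$OW == d[2L])
  xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = layer$in_ch)
  cols <- crossprod(layer$params$W, xm)                 # K_ x (P*N)
  yp <- col2im(cols, map, d[4L])
  y <- unpad_hw(yp, layer$pad, OH, OW)
  y <- sweep(y, 3L, layer$params$b, "+")
  tgt <- layer$target
  crop <- NULL
  if (!is.null(tgt)) {
    crop <- dim(y)[1:2]
    y <- fit_to_shape(y, tgt)
  }
  list(out = y, cache = list(xm = xm, map = map, in_dim = d,
                             raw_hw = c(OH, OW)))
}

tconv2d_backward <- function(layer, dout, cache) {
  d <- cache$in_dim
  if (!is.null(layer$target)) {
    dout <- fit_to_shape(dout, cache$raw_hw)
  }
  db <- apply(dout, 3L, sum)
  dyp <- pad_hw(dout, layer$pad)
  dcols <- im2col(dyp, cache$map)                       # K_ x (P*N)
  dW <- cache$xm %*% t(dcols)                           # in_ch x K_
  dxm <- layer$params$W %*% dcols                       # in_ch x (P*N)
  dx <- aperm(array(dxm, dim = c(layer$in_ch, d[1L], d[2L], d[4L])),
              c(2L, 3L, 1L, 4L))
  list(dx = dx, grads = list(W = dW, b = db))
}

# Crop or zero-pad the trailing spatial edge so dim(x)[1:2] == hw.
fit_to_shape <- function(x, hw) {
  d <- dim(x)
  if (d[1L] == hw[1L] && d[2L] == hw[2L]) return(x)
  out <- array(0, dim = c(hw[1L], hw[2L], d[3L], d[4L]))
  h <- min(d[1L], hw[1L]); w <- min(d[2L], hw[2L])
  out[seq_len(h), seq_len(w), , ] <- x[seq_len(h), seq_len(w), , , drop = FALSE]
  out
}

layer_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", ch = ch, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)))
}

# Channel statistics without transposing: view x as (H*W) x (C*N) and
# aggregate the per-(channel, sample) column stats over samples.
batchnorm_forward <- function(layer, x, training) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  C <- d[3L]
  N <- d[4L]
  m <- hw * N
  if (training) {
    xm <- matrix(x, hw, C * N)
    cn_mean <- .colMeans(xm, hw, C * N)
    mu <- .rowMeans(matrix(cn_mean, C, N), C, N)
    cn_sq <- .colMeans(xm * xm, hw, C * N)
    va <- .rowMeans(matrix(cn_sq, C, N), C, N) - mu^2
    va <- pmax(va, 0)
  } else {
    mu <- layer$buffers$running_mean
    va <- layer$buffers$running_var
  }
  ivar <- 1 / sqrt(va + layer$eps)
  mu_col <- rep(rep(mu, N), each = hw)
  iv_col <- rep(rep(ivar, N), each = hw)
  xhat <- (x - mu_col) * iv_col
  y <- xhat * rep(rep(layer$params$gamma, N), each = hw) +
    rep(rep(layer$params$beta, N), each = hw)
  dim(y) <- d
  upd <- NULL
  if (training) {
    mo <- layer$momentum
    upd <- list(
      running_mean = (1 - mo) * layer$buffers$running_mean + mo * mu,
      running_var = (1 - mo) * layer$buffers$running_var +
        mo * va * m / max(1, m - 1))
  }
  list(out = y, cache = list(xhat = xhat, ivar = ivar, d = d, m = m,
                             training = training),
       buffers = upd)
}

# Per-channel sums of an (H, W, C, N)-shaped vector.
channel_sums <- function(v, d) {
  hw <- d[1L] * d[2L]
  cn <- .colSums(matrix(v, hw, d[3L] * d[4L]), hw, d[3L] * d[4L])
  .rowSums(matrix(cn, d[3L], d[4L]), d[3L], d[4L])
}

batchnorm_backward <- function(layer, dout, cache) {
  d <- cache$d
  hw <- d[1L] * d[2L]
  N <- d[4L]
  dgamma <- channel_sums(dout * cache$xhat, d)
  dbeta <- channel_sums(dout, d)
  dxhat <- dout * rep(rep(layer$params$gamma, N), each = hw)
  iv_col <- rep(rep(cache$ivar, N), each = hw)
  if (cache$training) {
    m <- cache$m
    mean_dxhat <- channel_sums(dxhat, d) / m
    mean_dxx <- channel_sums(dxhat * cache$xhat, d) / m
    dx <- (dxhat - rep(rep(mean_dxhat, N), each = hw) -
             cache$xhat * rep(rep(mean_dxx, N), each = hw)) * iv_col
  } else {
    dx <- dxhat * iv_col
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layer_leakyrelu <- function(slope = 0.2) {
  list(type = "leakyrelu", slope = slope, params = list())
}

leakyrelu_forward <- function(layer, x, training) {
  fac <- layer$slope + (1 - layer$slope) * (x > 0)
  list(out = x * fac, cache = list(fac = fac))
}

leakyrelu_backward <- function(layer, dout, cache) {
  list(dx = dout * cache$fac, grads = list())
}

layer_maxpool <- function(size = 2L) {
  list(type = "maxpool", size = size, params = list())
}

maxpool_forward <- function(layer, x, training) {
  s <- layer$size
  d <- dim(x)
  H2 <- d[1L] %/% s
  W2 <- d[2L] %/% s
  cand <- vector("list", s * s)
  k <- 0L
  for (dw in seq_len(s)) for (dh in seq_len(s)) {
    k <- k + 1L
    cand[[k]] <- x[seq.int(dh, by = s, length.out = H2),
                   seq.int(dw, by = s, length.out = W2), , , drop = FALSE]
  }
  out <- cand[[1L]]
  arg <- array(1L, dim = dim(out))
  for (k in seq_along(cand)[-1L]) {
    better <- cand[[k]] > out             # strict: first max wins ties
    out[better] <- cand[[k]][better]
    arg[better] <- k
  }
  list(out = out, cache = list(arg = arg, d = d, H2 = H2, W2 = W2))
}

maxpool_backward <- function(layer, dout, cache) {
  s <- layer$size
  dx <- array(0, dim = cache$d)
  k <- 0L
  for (dw in seq_len(s)) for (dh in seq_len(s)) {
    k <- k + 1L
    mask <- cache$arg == k
    slab <- array(0, dim = dim(dout))
    slab[mask] <- dout[mask]
    dx[seq.int(dh, by = s, length.out = cache$H2),
       seq.int(dw, by = s, length.out = cache$W2), , ] <-
      dx[seq.int(dh, by = s, length.out = cache$H2),
         seq.int(dw, by = s, length.out = cache$W2), , , drop = FALSE] + slab
  }
  list(dx = dx, grads = list())
}

layer_dropout <- function(rate = 0.25) {
  list(type = "dropout", rate = rate, params = list())
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- array(stats::runif(length(x)) < keep, dim = dim(x)) / keep
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, dout, cache) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

# Squeeze-and-excitation: global average pool per channel, bottleneck MLP
# (LeakyReLU then logistic gate), channel-wise rescale of the input.
layer_se <- function(ch, reduction = 8L, slope = 0.2) {
  hidden <- max(1L, ceiling(ch / reduction))
  list(type = "se", ch = ch, hidden = hidden, slope = slope,
       params = list(W1 = matrix(he_init(hidden * ch, ch), hidden, ch),
                     b1 = numeric(hidden),
                     W2 = matrix(he_init(ch * hidden, hidden), ch, hidden),
                     b2 = numeric(ch)))
}

se_forward <- function(layer, x, training) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  xm <- matrix(x, nrow = hw)                        # hw x (C*N)
  z <- matrix(colMeans(xm), d[3L], d[4L])           # C x N (squeeze)
  a1 <- layer$params$W1 %*% z + layer$params$b1
  h1 <- ifelse(a1 > 0, a1, layer$slope * a1)
  a2 <- layer$params$W2 %*% h1 + layer$params$b2
  g <- sigmoid(a2)                                  # C x N gates
  gfull <- rep(as.numeric(g), each = hw)
  y <- x * array(gfull, dim = d)
  list(out = y, cache = list(x = x, z = z, a1 = a1, h1 = h1, g = g,
                             d = d, hw = hw))
}

se_backward <- function(layer, dout, cache) {
  d <- cache$d
  hw <- cache$hw
  gfull <- array(rep(as.numeric(cache$g), each = hw), dim = d)
  dx1 <- dout * gfull
  dg <- matrix(colSums(matrix(dout * cache$x, nrow = hw)), d[3L], d[4L])
  da2 <- dg * cache$g * (1 - cache$g)
  dW2 <- da2 %*% t(cache$h1)
  db2 <- rowSums(da2)
  dh1 <- crossprod(layer$params$W2, da2)
  da1 <- ifelse(cache$a1 > 0, dh1, layer$slope * dh1)
  dW1 <- da1 %*% t(cache$z)
  db1 <- rowSums(da1)
  dz <- crossprod(layer$params$W1, da1)             # C x N
  dx2 <- array(rep(as.numeric(dz), each = hw) / hw, dim = d)
  list(dx = dx1 + dx2,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# SAGAN-style self-attention over spatial locations with a learnable
# residual scale initialized at zero (identity map at initialization).
layer_attention <- function(ch, key_dim = NULL) {
  kd <- key_dim %||% max(1L, ch %/% 8L)
  list(type = "attention", ch = ch, key_dim = kd,
       params = list(Wq = matrix(he_init(kd * ch, ch), kd, ch),
                     Wk = matrix(he_init(kd * ch, ch), kd, ch),
                     Wv = matrix(he_init(ch * ch, ch), ch, ch),
                     gamma = 0))
}

attention_forward <- function(layer, x, training) {
  d <- dim(x)
  M <- d[1L] * d[2L]
  N <- d[4L]
  y <- x
  per <- vector("list", N)
  for (n in seq_len(N)) {
    xm <- t(matrix(x[, , , n], M, d[3L]))           # C x M
    q <- layer$params$Wq %*% xm
    k <- layer$params$Wk %*% xm
    v <- layer$params$Wv %*% xm
    E <- crossprod(q, k)                            # M x M, E[i,j]=q_i.k_j
    A <- softmax_cols(E)                            # weights over i per j
    o <- v %*% A                                    # C x M
    y[, , , n] <- array(t(o) * layer$params$gamma, dim = d[1:3]) +
      array(x[, , , n], dim = d[1:3])
    per[[n]] <- list(xm = xm, q = q, k = k, v = v, A = A, o = o)
  }
  list(out = y, cache = list(per = per, d = d, M = M))
}

attention_backward <- function(layer, dout, cache) {
  d <- cache$d
  M <- cache$M
  N <- d[4L]
  dx <- dout
  dWq <- matrix(0, nrow(layer$params$Wq), ncol(layer$params$Wq))
  dWk <- dWq * 0; dWk <- matrix(0, nrow(layer$params$Wk), ncol(layer$params$Wk))
  dWv <- matrix(0, nrow(layer$params$Wv), ncol(layer$params$Wv))
  dgamma <- 0
  g <- layer$params$gamma
  for (n in seq_len(N)) {
    p <- cache$per[[n]]
    dy <- t(matrix(dout[, , , n], M, d[3L]))        # C x M
    dgamma <- dgamma + sum(dy * p$o)
    do <- g * dy
    dv <- do %*% t(p$A)
    dA <- crossprod(p$v, do)                        # M x M
    # column-wise softmax backward
    dE <- p$A * sweep(dA, 2L, colSums(p$A * dA))
    dq <- p$k %*% t(dE)
    dk <- p$q %*% dE
    dWq <- dWq + dq %*% t(p$xm)
    dWk <- dWk + dk %*% t(p$xm)
    dWv <- dWv + dv %*% t(p$xm)
    dxm <- crossprod(layer$params$Wq, dq) +
      crossprod(layer$params$Wk, dk) +
      crossprod(layer$params$Wv, dv)
    dx[, , , n] <- array(dx[, , , n], dim = d[1:3]) +
      array(t(dxm), dim = d[1:3])
  }
  list(dx = dx, grads = list(Wq = dWq, Wk = dWk, Wv = dWv, gamma = dgamma))
}

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(he_init(out_dim * in_dim, in_dim),
                                out_dim, in_dim),
                     b = numeric(out_dim)))
}

dense_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- matrix(x, nrow = layer$in_dim)              # D x N
  out <- layer$params$W %*% xm + layer$params$b
  list(out = out, cache = list(xm = xm, d = d))
}

dense_backward <- function(layer, dout, cache) {
  dW <- dout %*% t(cache$xm)
  db <- rowSums(dout)
  dxm <- crossprod(layer$params$W, dout)
  list(dx = array(dxm, dim = cache$d), grads = list(W = dW, b = db))
}

layer_sigmoid <- function() list(type = "sigmoid", params = list())

sigmoid_forward <- function(layer, x, training) {
  y <- sigmoid(x)
  list(out = y, cache = list(y = y))
}

sigmoid_backward <- function(layer, dout, cache) {
  list(dx = dout * cache$y * (1 - cache$y), grads = list())
}

## ---- dispatch ------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv2d = conv2d_forward(layer, x, training),
    tconv2d = tconv2d_forward(layer, x, training),
    batchnorm = batchnorm_forward(layer, x, training),
    leakyrelu = leakyrelu_forward(layer, x, training),
    maxpool = maxpool_forward(layer, x, training),
    dropout = dropout_forward(layer, x, training),
    se = se_forward(layer, x, training),
    attention = attention_forward(layer, x, training),
    dense = dense_forward(layer, x, training),
    sigmoid = sigmoid_forward(layer, x, training),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv2d = conv2d_backward(layer, dout, cache),
    tconv2d = tconv2d_backward(layer, dout, cache),
    batchnorm = batchnorm_backward(layer, dout, cache),
    leakyrelu = leakyrelu_backward(layer, dout, cache),
    maxpool = maxpool_backward(layer, dout, cache),
    dropout = dropout_backward(layer, dout, cache),
    se = se_backward(layer, dout, cache),
    attention = attention_backward(layer, dout, cache),
    dense = dense_backward(layer, dout, cache),
    sigmoid = sigmoid_backward(layer, dout, cache),
    stop("unknown layer type: ", layer$type)
  )
}

# Run a list of layers; returns final output, per-layer caches, and any
# batch-norm buffer updates.
net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  taps <- list()
  buffers <- list()
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
    if (!is.null(res$buffers)) buffers[[as.character(i)]] <- res$buffers
    tap <- layers[[i]]$tap
    if (!is.null(tap)) taps[[tap]] <- x
  }
  list(out = x, caches = caches, taps = taps, buffers = buffers)
}

# Backward pass through a layer list. `dout` is the gradient at the final
# output; `dtaps` optionally injects extra gradients at tapped layers
# (added where the tap was recorded).
net_backward <- function(layers, fwd, dout, dtaps = NULL) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    tap <- layers[[i]]$tap
    if (!is.null(tap) && !is.null(dtaps[[tap]])) {
      dout <- dout + dtaps[[tap]]
    }
    res <- layer_backward(layers[[i]], dout, fwd$caches[[i]])
    dout <- res$dx
    grads[[i]] <- res$grads
  }
  list(dx = dout, grads = grads)
}

apply_buffer_updates <- function(layers, buffers) {
  for (nm in names(buffers)) {
    i <- as.integer(nm)
    layers[[i]]$buffers <- utils::modifyList(layers[[i]]$buffers,
                                             buffers[[nm]])
  }
  layers
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Sum two grads lists shaped like net layers' params.
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    for (nm in names(b[[i]])) {
      a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
    }
  }
  a
}
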