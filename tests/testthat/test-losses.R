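# Loss functions: hand-computed examples, brute-force Gram oracle,
# identity configurations, asymmetry and the decomposition identity.

test_that("classification/semantic loss matches closed forms", {
  expect_equal(classification_loss(c(1, 0, 0, 0), 1L), 0)
  expect_equal(classification_loss(rep(0.25, 4), 3L), log(4))
  expect_equal(classification_loss(c(0.7, 0.1, 0.1, 0.1), 1L), -log(0.7))
  expect_equal(semantic_loss(rep(0.5, 2), 2L), log(2))
  expect_equal(semantic_loss(c(0.9, 0.1), 2L), -log(0.1))
  # zero probability at the truth is clamped, never -Inf
  expect_true(is.finite(classification_loss(c(1, 0), 2L)))
  expect_error(classification_loss(c(0.5, 0.5), 3L), "label")
})

test_that("gram equals brute-force inner products and is symmetric PSD", {
  expect_equal(gram(matrix(c(1, 3, 2, 4), 2L)),   # h = [[1,2],[3,4]]
               matrix(c(5, 11, 11, 25), 2L))
  expect_equal(gram(matrix(0, 3L, 5L)), matrix(0, 3L, 3L))
  set.seed(41)
  for (rep_ in 1:3) {
    h <- matrix(stats::rnorm(24), 4L, 6L)
    g <- gram(h)
    brute <- matrix(0, 4L, 4L)
    for (i in 1:4) for (j in 1:4) {
      for (m in 1:6) brute[i, j] <- brute[i, j] + h[i, m] * h[j, m]
    }
    expect_lt(max(abs(g - brute)), 1e-12)
    expect_equal(g, t(g))
    expect_true(min(eigen(g, symmetric = TRUE)$values) > -1e-10)
  }
})

test_that("style loss is zero at identity, non-negative, and asymmetric", {
  set.seed(42)
  h <- list(h1 = matrix(stats::rnorm(12), 3L), h2 = matrix(stats::rnorm(8), 2L))
  expect_equal(style_loss(h, h), 0)
  g <- list(h1 = matrix(stats::rnorm(12), 3L), h2 = matrix(stats::rnorm(8), 2L))
  ab <- style_loss(h, g)
  ba <- style_loss(g, h)
  expect_gte(ab, 0)
  expect_gte(ba, 0)
  expect_false(isTRUE(all.equal(ab, ba)))        # KL direction is fixed
  # single-entry Grams softmax to 1 on both sides: no style signal
  expect_equal(style_loss(list(matrix(1, 1L, 1L)),
                          list(matrix(2, 1L, 1L))), 0)
  # batch arrays sum over samples
  hb <- list(array(stats::rnorm(24), dim = c(3L, 4L, 2L)))
  gb <- list(array(stats::rnorm(24), dim = c(3L, 4L, 2L)))
  per <- style_loss(list(hb[[1L]][, , 1L]), list(gb[[1L]][, , 1L])) +
    style_loss(list(hb[[1L]][, , 2L]), list(gb[[1L]][, , 2L]))
  expect_equal(style_loss(hb, gb), per)
  expect_error(style_loss(list(matrix(1, 2L, 2L)),
                          list(matrix(1, 3L, 2L))),
               class = "ssstn_shape_error")
})

test_that("content loss is the per-layer MSE averaged over samples", {
  expect_equal(content_loss(list(matrix(1, 1L, 2L)),
                            list(matrix(0, 1L, 2L))), 1)
  h <- list(matrix(stats::rnorm(10), 2L))
  expect_equal(content_loss(h, h), 0)
  g <- list(matrix(stats::rnorm(10), 2L))
  expect_equal(content_loss(lapply(h, function(x) 3 * x),
                            lapply(g, function(x) 3 * x)),
               9 * content_loss(h, g))           # quadratic scaling
  # two samples: mean of the per-sample values
  hb <- list(array(stats::rnorm(12), dim = c(2L, 3L, 2L)))
  gb <- list(array(stats::rnorm(12), dim = c(2L, 3L, 2L)))
  per <- c(content_loss(list(hb[[1L]][, , 1L]), list(gb[[1L]][, , 1L])),
           content_loss(list(hb[[1L]][, , 2L]), list(gb[[1L]][, , 2L])))
  expect_equal(content_loss(hb, gb), mean(per))
})

test_that("total loss combines components with the published weights", {
  rep_ <- total_loss(1, 2, 3, loss_weights(0.1, 1, 1))
  expect_equal(rep_$total, 5.1)
  expect_equal(total_loss(4, 5, 6, loss_weights(0, 0, 0))$total, 0)
  # decomposition identity on random components
  set.seed(43)
  for (i in 1:5) {
    s <- stats::runif(3, 0, 10)
    w <- loss_weights(stats::runif(1), stats::runif(1), stats::runif(1))
    r <- total_loss(s[1L], s[2L], s[3L], w)
    expect_equal(r$total,
                 w$alpha * r$style + w$beta_w * r$content +
                   w$gamma * r$semantic,
                 tolerance = 1e-9)
  }
  expect_error(loss_weights(-0.1, 1, 1), "alpha")
  # zeroing one weight reproduces each ablation variant
  expect_equal(total_loss(1, 2, 3, loss_weights(0, 1, 1))$total, 5)  # no style
  expect_equal(total_loss(1, 2, 3, loss_weights(0.1, 0, 1))$total, 3.1)
  expect_equal(total_loss(1, 2, 3, loss_weights(0.1, 1, 0))$total, 2.1)
})

test_that("style gradient matches finite differences on a toy layer", {
  set.seed(44)
  ht <- matrix(stats::rnorm(12), 3L, 4L)
  q <- ssstn:::softmax_vec(as.numeric(gram(matrix(stats::rnorm(12), 3L))))
  f <- function(hv) {
    h <- matrix(hv, 3L, 4L)
    p <- ssstn:::softmax_vec(as.numeric(gram(h)))
    sum(p * (log(pmax(p, 1e-12)) - log(pmax(q, 1e-12))))
  }
  g_an <- ssstn:::style_grad_one(ht, q)
  g_num <- num_grad(f, as.numeric(ht))
  expect_lt(max(abs(as.numeric(g_an) - g_num)), 1e-7)
})
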