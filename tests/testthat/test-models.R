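# Classifier and generator architectures: shapes, determinism, feature
# taps, SE gating, self-attention, parameter counts, checkpoints.

test_that("classifier forward yields normalized predictions and two taps", {
  spec <- classifier_spec(2L, 12L, 14L, K = 4L, conv_channels = c(4L, 8L),
                          se_reduction = 2L)
  model <- build_classifier(spec, seed = 1L)
  img <- array(stats::runif(2 * 12 * 14), dim = c(2L, 12L, 14L))
  out <- classifier_forward(model, img)
  expect_equal(colSums(out$prediction$probabilities), 1, tolerance = 1e-6)
  expect_equal(nrow(out$prediction$logits), 4L)
  expect_length(out$features, 2L)
  # strictly decreasing spatial size across the two pooled blocks
  expect_lt(dim(out$features$h2)[2L], dim(out$features$h1)[2L])
  # zero image still gives finite, normalized output
  z <- classifier_forward(model, img * 0)
  expect_true(all(is.finite(z$prediction$logits)))
  expect_equal(sum(z$prediction$probabilities), 1, tolerance = 1e-6)
  # evaluation mode is bit-deterministic
  out2 <- classifier_forward(model, img)
  expect_identical(out$prediction$logits, out2$prediction$logits)
})

test_that("shape mismatches raise errors naming the offending axis", {
  spec <- classifier_spec(2L, 12L, 14L, K = 2L, conv_channels = c(4L, 8L))
  model <- build_classifier(spec, seed = 1L)
  bad <- array(0, dim = c(3L, 12L, 14L))
  expect_error(classifier_forward(model, bad), "channels",
               class = "ssstn_shape_error")
  bad2 <- array(0, dim = c(2L, 9L, 14L))
  expect_error(classifier_forward(model, bad2), "frequencies",
               class = "ssstn_shape_error")
})

test_that("generator output dims equal input dims for both montages", {
  for (dims in list(c(22L, 64L, 225L), c(3L, 64L, 225L))) {
    spec <- generator_spec(dims[1L], dims[2L], dims[3L],
                           enc_channels = c(4L, 6L, 8L))
    gen <- build_generator(spec, seed = 2L)
    img <- array(stats::runif(prod(dims)), dim = dims)
    out <- generator_forward(gen, img)
    expect_equal(dim(out), dims)
    expect_true(all(is.finite(out)))
  }
})

test_that("attention scale zero makes the generator attention-free", {
  spec <- generator_spec(2L, 12L, 14L, enc_channels = c(4L, 6L, 8L))
  gen <- build_generator(spec, seed = 3L)
  img <- array(stats::runif(2 * 12 * 14), dim = c(2L, 12L, 14L))
  base <- generator_forward(gen, img)
  # attention layers start at gamma = 0; scrambling their projections
  # must not change the output
  gen2 <- gen
  for (i in seq_along(gen2$layers)) {
    if (gen2$layers[[i]]$type == "attention") {
      gen2$layers[[i]]$params$Wq <- gen2$layers[[i]]$params$Wq * 10 + 1
      gen2$layers[[i]]$params$Wv <- gen2$layers[[i]]$params$Wv * -3
    }
  }
  expect_identical(base, generator_forward(gen2, img))
})

test_that("standalone SE block gates as specified", {
  set.seed(31)
  h <- matrix(stats::rnorm(6 * 10), 6L)
  expect_identical(se_block(h, identity_gate = TRUE), h)
  out <- se_block(h, reduction = 2L)
  expect_equal(dim(out), dim(h))
  # logistic gates lie in (0,1): per-channel magnitude can only shrink
  expect_true(all(abs(out) <= abs(h) + 1e-12))
  hz <- h
  hz[2L, ] <- 0
  expect_true(all(se_block(hz, reduction = 2L)[2L, ] == 0))
})

test_that("standalone self-attention honors its degenerate cases", {
  set.seed(32)
  h <- matrix(stats::rnorm(4 * 6), 4L)
  expect_equal(self_attention(h, gamma = 0), h)
  # single spatial location: affinity is 1, output = input + gamma * Wv h
  h1 <- matrix(c(1, -2, 0.5, 3), 4L, 1L)
  Wv <- diag(4L) * 2
  params <- list(Wq = matrix(1, 1L, 4L), Wk = matrix(1, 1L, 4L), Wv = Wv)
  expect_equal(self_attention(h1, params = params, gamma = 0.5),
               h1 + 0.5 * Wv %*% h1)
  # permutation equivariance over spatial locations (2 x 3 toy map)
  hp <- matrix(stats::rnorm(2 * 3), 2L, 3L)
  params2 <- list(Wq = matrix(stats::rnorm(2), 1L, 2L),
                  Wk = matrix(stats::rnorm(2), 1L, 2L),
                  Wv = matrix(stats::rnorm(4), 2L, 2L))
  perm <- c(3L, 1L, 2L)
  a <- self_attention(hp[, perm], params = params2, gamma = 0.8)
  b <- self_attention(hp, params = params2, gamma = 0.8)[, perm]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("parameter counts match hand-computed totals", {
  spec <- classifier_spec(3L, 16L, 23L, K = 2L, conv_channels = c(16L, 32L),
                          se_reduction = 8L)
  model <- build_classifier(spec, seed = 1L)
  conv1 <- 16 * (5 * 5 * 3) + 16
  bn1 <- 2 * 16
  se1 <- 2 * 16 + 2 + 16 * 2 + 16       # W1 (2x16), b1, W2 (16x2), b2
  conv2 <- 32 * (5 * 5 * 16) + 32
  bn2 <- 2 * 32
  se2 <- 4 * 32 + 4 + 32 * 4 + 32
  dense <- 2 * (4 * 5 * 32) + 2          # 16x23 -> 8x11 -> 4x5 spatial
  expect_equal(n_parameters(model),
               conv1 + bn1 + se1 + conv2 + bn2 + se2 + dense)
})

test_that("checkpoints round-trip and verify the embedded spec", {
  spec <- classifier_spec(2L, 8L, 8L, K = 2L, conv_channels = c(4L, 8L))
  model <- build_classifier(spec, seed = 5L)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, path)
  back <- load_checkpoint(path, expected_spec = spec)
  img <- array(stats::runif(2 * 8 * 8), dim = c(2L, 8L, 8L))
  expect_identical(classifier_forward(model, img)$prediction$logits,
                   classifier_forward(back, img)$prediction$logits)
  other <- classifier_spec(2L, 8L, 8L, K = 4L, conv_channels = c(4L, 8L))
  expect_error(load_checkpoint(path, expected_spec = other), "spec")
})
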