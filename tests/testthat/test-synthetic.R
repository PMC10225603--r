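# Synthetic ERD/ERS simulator: determinism, balance, spectral content,
# and the class-dependent post-cue power modulation.

test_that("identical profile and seed give bit-identical output", {
  p <- subject_profile("a", erd_depth = 0.7, snr = 3, seed = 9L)
  t1 <- simulate_trial(p, 2L, 4L, 1.5, 250, K = 4L)
  t2 <- simulate_trial(p, 2L, 4L, 1.5, 250, K = 4L)
  expect_identical(t1, t2)
  d1 <- simulate_subject(p, 3L, n_channels = 4L, duration_s = 1.0,
                         fs = 250, K = 4L)
  d2 <- simulate_subject(p, 3L, n_channels = 4L, duration_s = 1.0,
                         fs = 250, K = 4L)
  expect_identical(d1, d2)
})

test_that("trials have the contracted shape, labels and finite values", {
  p <- subject_profile("a", seed = 2L)
  tr <- simulate_trial(p, 1L, 5L, 2.2, 200, K = 2L)
  expect_equal(dim(tr$data), c(5L, round(2.2 * 200)))
  expect_true(all(is.finite(tr$data)))
  expect_equal(tr$t0_s, -0.5)
  ds <- simulate_subject(p, 72L, n_channels = 3L, duration_s = 1.0,
                         fs = 100, K = 4L)
  expect_equal(dim(ds$data)[1L], 288L)           # 72 trials x 4 classes
  expect_equal(as.integer(table(ds$labels)), rep(72L, 4L))
  ds2 <- simulate_subject(p, 1L, n_channels = 2L, duration_s = 1.0,
                          fs = 100, K = 2L)
  expect_equal(sort(ds2$labels), c(1L, 2L))
})

test_that("invalid arguments are rejected with labeled errors", {
  p <- subject_profile("a", seed = 1L)
  expect_error(simulate_trial(p, 5L, 3L, 1, 250, K = 4L), "label")
  expect_error(simulate_trial(p, 0L, 3L, 1, 250, K = 4L), "label")
  expect_error(simulate_trial(p, 1L, 3L, -1, 250, K = 4L), "duration")
  expect_error(simulate_trial(p, 1L, 3L, 1, 30, K = 4L), "fs")
  expect_error(subject_profile("a", erd_depth = 1.2), "erd_depth")
  expect_error(subject_profile("a", snr = -1), "snr")
  expect_error(subject_profile("a", mu_center_hz = 45), "mu_center_hz")
  expect_error(
    make_population(subject_profile("x", seed = 1),
                    list(subject_profile("x", seed = 2)),
                    n_trials_per_class = 1L, n_channels = 2L,
                    duration_s = 0.5, fs = 100, K = 2L),
    "duplicate")
})

test_that("oscillatory power concentrates near the configured band centers", {
  p <- subject_profile("a", erd_depth = 0, snr = 12, mu_center_hz = 9,
                       beta_center_hz = 24, seed = 5L)
  tr <- simulate_trial(p, 1L, 1L, 8, 250, K = 2L, t0_s = 0)
  x <- tr$data[1L, ]
  w <- welch_psd(x, 250)
  in_mu <- w$freq >= 7 & w$freq <= 11
  in_be <- w$freq >= 22 & w$freq <= 26
  out_band <- (w$freq >= 13 & w$freq <= 20) | (w$freq >= 28 & w$freq <= 40)
  expect_gt(mean(w$psd[in_mu]), 5 * mean(w$psd[out_band]))
  expect_gt(mean(w$psd[in_be]), 5 * mean(w$psd[out_band]))
})

test_that("ERD lowers post-cue mu power on the affected channel for its class", {
  # Welch-periodogram oracle over 100 trials: with erd_depth = 0.8 the
  # class-1 carrier channel must lose mu power after the cue relative to
  # class-2 trials; with erd_depth = 0 the two classes must be
  # indistinguishable (zero effect size is the null by construction).
  run_powers <- function(erd) {
    p <- subject_profile("a", erd_depth = erd, snr = 5, mu_center_hz = 10,
                         channel_topography = list(1L, 2L), seed = 31L)
    per_class <- lapply(1:2, function(k) {
      vapply(1:50, function(j) {
        tr <- simulate_trial(p, k, 2L, 4.5, 250, K = 2L,
                             seed = 100000L * k + j)
        post <- tr$data[1L, (0.5 * 250 + 1):(4.5 * 250)]
        band_power(post, 250, 8, 13)
      }, numeric(1L))
    })
    per_class
  }
  strong <- run_powers(0.8)
  expect_lt(mean(strong[[1L]]), 0.5 * mean(strong[[2L]]))
  flat <- run_powers(0)
  expect_gt(stats::t.test(flat[[1L]], flat[[2L]])$p.value, 0.01)
})

test_that("populations share dimensions and separate expert from illiterate", {
  pop <- make_population(
    subject_profile("e", erd_depth = 0.9, snr = 8, seed = 1L),
    list(subject_profile("i1", erd_depth = 0.15, snr = 0.8, seed = 2L),
         subject_profile("i2", erd_depth = 0.1, snr = 0.5, seed = 3L)),
    n_trials_per_class = 2L, n_channels = 3L, duration_s = 0.8,
    fs = 125, K = 2L)
  expect_named(pop, c("e", "i1", "i2"))
  for (d in pop) {
    expect_equal(dim(d$data), dim(pop[[1L]]$data))
    expect_equal(d$fs, 125)
    expect_equal(d$K, 2L)
  }
})
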