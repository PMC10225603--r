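# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; expensive intermediates are cached per test run.

.fix_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, expr) {
  hit <- .fix_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fix_cache[[key]] <- val
  val
}

# ---- desk-scale study conditions (stated in the methods vignette) -------
# 2-class, 3-electrode recordings at 250 Hz, 4.5 s epochs; 16 log-spaced
# analysis frequencies 4-40 Hz pooled by 48 -> 16 x 23 images; narrow
# desk-scale network widths.

desk_freqs <- function() default_freqs(4, 40, 16)

desk_cls_spec <- function() {
  classifier_spec(3L, 16L, 23L, K = 2L, conv_channels = c(16L, 32L))
}

desk_gen_spec <- function() {
  generator_spec(3L, 16L, 23L, enc_channels = c(16L, 32L, 64L))
}

expert_fixture <- function(seed) {
  subject_profile("expert", erd_depth = 0.9, snr = 8, mu_center_hz = 10,
                  beta_center_hz = 22,
                  channel_topography = list(1L, 3L), seed = seed)
}

illiterate_fixture <- function(id, seed) {
  subject_profile(id, erd_depth = 0.15, snr = 0.5, mu_center_hz = 12,
                  beta_center_hz = 26,
                  channel_topography = list(2L, 1L), seed = seed)
}

prep_subject <- function(profile, n_per_class = 40L) {
  cwt_transform(
    preprocess_epochs(simulate_subject(profile, n_per_class,
                                       n_channels = 3L, duration_s = 4.5,
                                       fs = 250, K = 2L)),
    freqs_hz = desk_freqs(), time_downsample = 48L)
}

# ---- cheap synthetic scalogram sets for plumbing tests ------------------
# Class-separable random images, no CWT involved.
toy_scalogram_set <- function(n_per_class = 8L, K = 2L, C = 2L, F_ = 8L,
                              T_ = 10L, seed = 1L, subject_id = "toy",
                              sep = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * K
    labels <- sample(rep(seq_len(K), n_per_class))
    images <- array(runif(n * C * F_ * T_, 0, 0.5), dim = c(n, C, F_, T_))
    for (i in seq_len(n)) {
      rows <- ((labels[i] - 1L) %% F_) + seq_len(2L)
      images[i, 1L, rows, ] <- pmin(1, images[i, 1L, rows, ] + sep * 0.5)
    }
    structure(list(images = images, labels = labels,
                   freqs_hz = seq_len(F_), times_s = seq_len(T_),
                   K = as.integer(K), subject_id = subject_id,
                   normalized = TRUE),
              class = "scalogram_set")
  })
}

# ---- oracles -------------------------------------------------------------

# Welch power spectral density: mean periodogram over 50%-overlapping
# Hann-windowed segments.
welch_psd <- function(x, fs, seg = 256L) {
  step <- seg %/% 2L
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  acc <- 0
  for (s0 in starts) {
    xs <- x[s0:(s0 + seg - 1L)] * win
    acc <- acc + abs(fft(xs))^2
  }
  p <- acc / length(starts) / sum(win^2) / fs
  freq <- seq(0, fs, length.out = seg + 1L)[seq_len(seg)]
  list(freq = freq[seq_len(seg %/% 2L)], psd = p[seq_len(seg %/% 2L)])
}

band_power <- function(x, fs, lo, hi) {
  w <- welch_psd(x, fs)
  sel <- w$freq >= lo & w$freq <= hi
  mean(w$psd[sel])
}

# Central finite-difference gradient.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

reshape_like <- function(pv, p0) {
  if (is.null(dim(p0))) as.numeric(pv) else array(pv, dim = dim(p0))
}
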