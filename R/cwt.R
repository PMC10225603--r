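#' Morlet wavelet parameters
#'
#' @param beta_adm Positive admissibility/width parameter of the Morlet
#'   wavelet: larger values narrow the time support and widen the frequency
#'   support. Default 1, balancing spectral and temporal resolution.
#' @return A `morlet_params` object.
#' @export
morlet_params <- function(beta_adm = 1) {
  check_number(beta_adm, "beta_adm", lower = 0, strict_lower = TRUE)
  structure(list(beta_adm = beta_adm), class = "morlet_params")
}

#' The (real) Morlet mother wavelet
#'
#' `psi(t) = exp(-beta^2 t^2 / 2) * cos(pi t)`: a cosine of frequency 0.5
#' cycles per unit time under a Gaussian envelope. Even in `t`.
#'
#' @param t Unitless time (vectorized).
#' @param params A [morlet_params()].
#' @return Numeric vector of wavelet values.
#' @export
morlet <- function(t, params = morlet_params()) {
  stopifnot(inherits(params, "morlet_params"))
  exp(-params$beta_adm^2 * t^2 / 2) * cos(pi * t)
}

#' Map an analysis frequency to a wavelet scale
#'
#' The mother wavelet oscillates at 0.5 cycles per unit time, so a scale
#' `a` (in samples) analyzes `f = 0.5 * fs / a` Hz; inverting gives
#' `a = 0.5 * fs / f`.
#'
#' @param f_hz Frequency in Hz, `0 < f_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param params A [morlet_params()] (the center frequency of this wavelet
#'   family does not depend on `beta_adm`; kept for interface symmetry).
#' @return Scale in samples.
#' @export
scale_for_frequency <- function(f_hz, fs, params = morlet_params()) {
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(f_hz)) || any(f_hz <= 0) || any(f_hz >= fs / 2)) {
    abort_arg("`f_hz` must satisfy 0 < f_hz < fs/2.", "f_hz")
  }
  0.5 * fs / f_hz
}

# Sampled, 1/sqrt(a)-normalized wavelet kernel at scale a (samples).
morlet_kernel <- function(a, params) {
  hw <- ceiling(7.5 * a / params$beta_adm)  # Gaussian tail < 1e-12
  u <- (-hw:hw) / a
  morlet(u, params) / sqrt(a)
}

#' Continuous wavelet transform of a 1-D signal
#'
#' Discrete approximation of the CWT integral
#' `X(a, b) = |a|^{-1/2} sum_t x(t) psi((t - b)/a)` on the sample grid, by
#' correlation with the sampled, scaled wavelet (the wavelet is even, so
#' correlation and convolution coincide). The wavelet is real, so the
#' coefficients are real; take `abs()` for a scalogram.
#'
#' @param x Finite numeric signal.
#' @param fs Sampling rate in Hz (metadata only; scales are in samples).
#' @param scales Positive scales in samples, one output row each.
#' @param params A [morlet_params()].
#' @param boundary `"symmetric"` (default, mirrors the signal to avoid edge
#'   ringing) or `"zero"` (zero padding; matches the plain truncated sum).
#' @return `length(scales)` x `length(x)` numeric matrix.
#' @export
cwt_coefficients <- function(x, fs, scales, params = morlet_params(),
                             boundary = c("symmetric", "zero")) {
  boundary <- match.arg(boundary)
  if (length(scales) == 0L) abort_arg("`scales` must be non-empty.")
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    abort_arg("`scales` must be positive and finite.", "scales")
  }
  if (any(!is.finite(x))) abort_arg("`x` must be finite.", "x")
  n <- length(x)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    k <- morlet_kernel(scales[si], params)
    hw <- (length(k) - 1L) %/% 2L
    xpad <- pad_signal(x, hw, boundary)
    out[si, ] <- fft_correlate(xpad, k)[seq_len(n)]
  }
  out
}

pad_signal <- function(x, hw, boundary) {
  n <- length(x)
  if (hw == 0L) return(x)
  if (boundary == "zero") return(c(numeric(hw), x, numeric(hw)))
  # symmetric reflection about the edge samples, tiling if the kernel is
  # longer than the signal
  left <- vapply((1L - hw):0L, function(i) x[reflect_index(i, n)], 0)
  right <- vapply((n + 1L):(n + hw), function(i) x[reflect_index(i, n)], 0)
  c(left, x, right)
}

# Reflect an out-of-range index into 1..n (mirror about the edge samples).
reflect_index <- function(i, n) {
  if (n == 1L) return(1L)
  period <- 2L * n - 2L
  j <- ((i - 1L) %% period)
  if (j < 0) j <- j + period
  j <- ifelse(j >= n, period - j, j)
  as.integer(j + 1L)
}

# Linear cross-correlation via FFT: r[b] = sum_j xpad[j + b - 1] * k[j],
# b = 1..(length(xpad) - length(k) + 1).
fft_correlate <- function(xpad, k) {
  np <- length(xpad)
  kp <- c(k, numeric(np - length(k)))
  r <- Re(stats::fft(stats::fft(xpad) * Conj(stats::fft(kp)),
                     inverse = TRUE)) / np
  r[seq_len(np - length(k) + 1L)]
}

#' Convert one epoch into a stacked per-electrode scalogram image
#'
#' Per electrode, the absolute CWT coefficients at the scales mapped from
#' `freqs_hz` are computed and mean-pooled along time by
#' `time_downsample`; the per-electrode scalograms are stacked on the
#' channel axis, giving a channels x frequencies x time image.
#'
#' @param trial A `trial` object.
#' @param freqs_hz Analysis frequencies in Hz (default 64 log-spaced points
#'   covering 4--40 Hz, the mu and beta range inside the passband).
#' @param params A [morlet_params()].
#' @param time_downsample Positive integer mean-pooling factor along time.
#' @param boundary Passed to [cwt_coefficients()].
#' @return A `scalogram` object: list with `values`
#'   (channels x frequencies x time, all `>= 0`), `freqs_hz`, `times_s`,
#'   `label`.
#' @export
epoch_to_scalogram <- function(trial, freqs_hz = default_freqs(),
                               params = morlet_params(),
                               time_downsample = 5L,
                               boundary = "symmetric") {
  stopifnot(inherits(trial, "trial"))
  time_downsample <- check_count(time_downsample, "time_downsample")
  n <- ncol(trial$data)
  if (time_downsample > n) {
    abort_arg("`time_downsample` exceeds the epoch length.",
              "time_downsample")
  }
  scales <- scale_for_frequency(freqs_hz, trial$fs, params)
  n_keep <- (n %/% time_downsample) * time_downsample
  t_out <- n_keep %/% time_downsample
  C <- nrow(trial$data)
  vals <- array(0, dim = c(C, length(freqs_hz), t_out))
  for (ch in seq_len(C)) {
    w <- abs(cwt_coefficients(trial$data[ch, ], trial$fs, scales, params,
                              boundary = boundary))
    w <- w[, seq_len(n_keep), drop = FALSE]
    # mean pooling along time
    dim(w) <- c(length(freqs_hz), time_downsample, t_out)
    vals[ch, , ] <- apply(w, c(1L, 3L), mean)
  }
  tt <- trial$t0_s + (seq_len(n) - 1L) / trial$fs
  tt <- tt[seq_len(n_keep)]
  dim(tt) <- c(time_downsample, t_out)
  structure(list(values = vals, freqs_hz = freqs_hz,
                 times_s = colMeans(tt), label = trial$label),
            class = "scalogram")
}

#' @rdname epoch_to_scalogram
#' @export
default_freqs <- function(fmin = 4, fmax = 40, n_freqs = 64L) {
  exp(seq(log(fmin), log(fmax), length.out = n_freqs))
}

#' Transform a whole epoched dataset into a scalogram image set
#'
#' Applies [epoch_to_scalogram()] to every trial and (by default) min-max
#' scales each image to `[0, 1]`, the bounded range the classifier and
#' generator expect.
#'
#' @param epochs An `eeg_epochs` object.
#' @inheritParams epoch_to_scalogram
#' @param normalize Min-max scale each trial's image to `[0, 1]`
#'   (default TRUE).
#' @return A `scalogram_set`: list with `images`
#'   (trials x channels x frequencies x time array), `labels`, `freqs_hz`,
#'   `times_s`, `K`, `subject_id`, `normalized`.
#' @export
cwt_transform <- function(epochs, freqs_hz = default_freqs(),
                          params = morlet_params(), time_downsample = 5L,
                          boundary = "symmetric", normalize = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_trials <- dim(epochs$data)[1L]
  first <- NULL
  images <- NULL
  for (i in seq_len(n_trials)) {
    tr <- structure(list(data = matrix(epochs$data[i, , ],
                                       nrow = dim(epochs$data)[2L]),
                         fs = epochs$fs, label = epochs$labels[i],
                         t0_s = epochs$t0_s), class = "trial")
    sc <- epoch_to_scalogram(tr, freqs_hz, params, time_downsample, boundary)
    v <- sc$values
    if (normalize) {
      rng <- range(v)
      v <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L]) else v * 0
    }
    if (is.null(images)) {
      first <- sc
      images <- array(0, dim = c(n_trials, dim(v)))
    }
    images[i, , , ] <- v
  }
  structure(list(images = images, labels = epochs$labels,
                 freqs_hz = first$freqs_hz, times_s = first$times_s,
                 K = epochs$K, subject_id = epochs$subject_id,
                 normalized = normalize),
            class = "scalogram_set")
}

#' @export
#' @method print scalogram_set
print.scalogram_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "<scalogram_set> subject %s: %d images of %d ch x %d freq x %d time, K = %d\n",
    x$subject_id, d[1L], d[2L], d[3L], d[4L], x$K))
  invisible(x)
}
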