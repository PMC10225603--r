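#' Zero-phase band-pass filter a trial
#'
#' Butterworth band-pass applied forward-backward (`signal::filtfilt`) per
#' channel, so the pass band is shaped twice and the phase response is zero
#' — ERD latencies are not shifted.
#'
#' @param trial A `trial` object.
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of the underlying one-pass design
#'   (default 6, which holds 50 Hz mains leakage under 5% after the
#'   double pass).
#' @return A `trial` of identical length.
#' @export
bandpass <- function(trial, low_hz = 0.5, high_hz = 40, order = 6L) {
  stopifnot(inherits(trial, "trial"))
  fs <- trial$fs
  check_number(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
  if (!(low_hz < high_hz)) abort_arg("`low_hz` must be < `high_hz`.")
  if (high_hz >= fs / 2) {
    abort_arg(sprintf("`high_hz` = %g reaches the Nyquist frequency %g.",
                      high_hz, fs / 2), "high_hz")
  }
  order <- check_count(order, "order")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- trial
  out$data <- t(apply(trial$data, 1L, function(ch) {
    signal::filtfilt(bf, ch)
  }))
  out
}

#' Exponential moving standardization
#'
#' Per channel, a running mean and running variance with exponential decay
#' track the signal; each sample is centered and scaled by them:
#' `m_t = (1-decay) m_{t-1} + decay x_t`,
#' `v_t = (1-decay) v_{t-1} + decay (x_t - m_t)^2`,
#' `x'_t = (x_t - m_t) / max(sqrt(v_t), eps)`. Initialization: `m_0 = x_1`,
#' `v_0 = 1`.
#'
#' @param trial A `trial` object.
#' @param decay Update weight in (0, 1); default 0.001.
#' @param eps Lower bound for the scale; must be > 0.
#' @return A `trial` of identical length.
#' @export
exponential_moving_standardize <- function(trial, decay = 1e-3, eps = 1e-4) {
  stopifnot(inherits(trial, "trial"))
  check_number(decay, "decay", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(eps, "eps", lower = 0, strict_lower = TRUE)
  out <- trial
  out$data <- t(apply(trial$data, 1L, ems_channel, decay = decay, eps = eps))
  out
}

ems_channel <- function(x, decay, eps) {
  n <- length(x)
  # recursive filter: m_t = (1-decay) m_{t-1} + decay x_t, m_0 = x_1
  m <- stats::filter(decay * x, 1 - decay, method = "recursive",
                     init = x[1L])
  m <- as.numeric(m)
  d2 <- (x - m)^2
  v <- stats::filter(decay * d2, 1 - decay, method = "recursive", init = 1)
  v <- as.numeric(v)
  (x - m) / pmax(sqrt(v), eps)
}

#' Extract a cue-locked epoch from a continuous recording
#'
#' @param continuous Channels x time numeric matrix.
#' @param cue_sample Sample index (1-based) of the cue.
#' @param fs Sampling rate in Hz.
#' @param pre_s Seconds kept before the cue (default 0.5).
#' @param post_s Seconds kept after the cue (default 4.0).
#' @param label Optional class label attached to the trial.
#' @return A `trial` of `round((pre_s + post_s) * fs)` samples with
#'   `t0_s = -pre_s`.
#' @export
extract_epoch <- function(continuous, cue_sample, fs, pre_s = 0.5,
                          post_s = 4.0, label = NA_integer_) {
  stopifnot(is.matrix(continuous))
  check_number(pre_s, "pre_s", lower = 0)
  check_number(post_s, "post_s", lower = 0, strict_lower = TRUE)
  n <- round((pre_s + post_s) * fs)
  start <- cue_sample - round(pre_s * fs)
  stop_ <- start + n - 1L
  if (start < 1L || stop_ > ncol(continuous)) {
    rlang::abort(sprintf(
      "epoch window [%d, %d] falls outside the recording (1..%d) for cue at %d",
      start, stop_, ncol(continuous), cue_sample),
      class = "ssstn_index_error")
  }
  structure(list(data = continuous[, start:stop_, drop = FALSE], fs = fs,
                 label = label, t0_s = -pre_s),
            class = "trial")
}

#' Preprocess every trial of an epoched dataset
#'
#' Applies the standard pipeline in order: band-pass filter, then
#' exponential moving standardization, per trial. Trial count, labels and
#' lengths are preserved.
#'
#' @param epochs An `eeg_epochs` object.
#' @inheritParams bandpass
#' @inheritParams exponential_moving_standardize
#' @return An `eeg_epochs` object.
#' @export
preprocess_epochs <- function(epochs, low_hz = 0.5, high_hz = 40,
                              order = 6L, decay = 1e-3, eps = 1e-4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1L])) {
    tr <- structure(list(data = epochs$data[i, , , drop = TRUE],
                         fs = epochs$fs, label = epochs$labels[i],
                         t0_s = epochs$t0_s), class = "trial")
    if (is.null(dim(tr$data))) tr$data <- matrix(tr$data, nrow = 1L)
    tr <- bandpass(tr, low_hz, high_hz, order)
    tr <- exponential_moving_standardize(tr, decay, eps)
    out$data[i, , ] <- tr$data
  }
  out
}
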