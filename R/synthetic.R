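#' Define a simulated motor-imagery subject
#'
#' A subject profile fixes everything that distinguishes one simulated
#' participant from another: how deep their event-related desynchronization
#' (ERD) is, how strong their sensorimotor rhythms are relative to the 1/f
#' background, where those rhythms sit in frequency, and which electrodes
#' carry the class-specific modulation. A high `erd_depth` and `snr` produce
#' a "BCI expert" whose trials a classifier separates easily; values near
#' zero produce a "BCI illiterate" stuck near chance.
#'
#' @param subject_id Character or integer label, unique within a population.
#' @param erd_depth Fraction in `[0, 1]`: post-cue amplitude attenuation of
#'   the class-relevant rhythm on that class's electrodes. 0 means no
#'   class information at all.
#' @param snr Linear signal-to-noise power ratio (oscillation power over
#'   1/f background power) on the carrying electrodes; must be `>= 0`.
#' @param mu_center_hz,beta_center_hz Centers of the mu and beta rhythms in
#'   Hz; both must lie inside the 0.5--40 Hz analysis passband.
#' @param channel_topography Optional list of length `K` mapping each class
#'   to the integer electrode indices that carry its ERD. Default: classes
#'   are assigned distinct, evenly spaced electrodes at simulation time.
#' @param seed Integer seed; identical (profile, sizes) input reproduces a
#'   bit-identical dataset.
#'
#' @return A `subject_profile` object (a named list).
#' @export
subject_profile <- function(subject_id, erd_depth = 0.6, snr = 2,
                            mu_center_hz = 10, beta_center_hz = 22,
                            channel_topography = NULL, seed = 1L) {
  check_number(erd_depth, "erd_depth", lower = 0, upper = 1)
  check_number(snr, "snr", lower = 0)
  check_number(mu_center_hz, "mu_center_hz", lower = 0.5, upper = 40,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(beta_center_hz, "beta_center_hz", lower = 0.5, upper = 40,
               strict_lower = TRUE, strict_upper = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(subject_id = as.character(subject_id), erd_depth = erd_depth,
         snr = snr, mu_center_hz = mu_center_hz,
         beta_center_hz = beta_center_hz,
         channel_topography = channel_topography, seed = seed),
    class = "subject_profile"
  )
}

# 1/f ("pink") background: white Gaussian noise shaped in the frequency
# domain by a 1/sqrt(f) amplitude envelope, unit-variance on output.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # two-sided spectrum
  env <- c(0, 1 / sqrt(f[-1L]))         # kill DC, 1/sqrt(f) elsewhere
  x <- Re(stats::fft(W * env, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrowband Gaussian oscillation centred at f0 with ~sigma_hz bandwidth,
# unit RMS. Realistic stand-in for a sensorimotor rhythm.
narrowband_noise <- function(n, fs, f0, sigma_hz = 0.8) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  fmir <- pmin(f, fs - f)
  env <- exp(-(fmir - f0)^2 / (2 * sigma_hz^2))
  x <- Re(stats::fft(W * env, inverse = TRUE)) / n
  x / stats::sd(x)
}

default_topography <- function(K, n_channels) {
  idx <- round(seq(1L, n_channels, length.out = K))
  # guarantee distinct channels when n_channels >= K
  if (anyDuplicated(idx) && n_channels >= K) idx <- seq_len(K)
  lapply(idx, identity)
}

#' Simulate one cue-locked motor-imagery trial
#'
#' Every channel receives unit-variance 1/f background noise plus mu- and
#' beta-band narrowband oscillations scaled to the profile's `snr`. After
#' the cue (`t >= 0`), the oscillation amplitude on the electrodes assigned
#' to `label` is multiplied by `1 - erd_depth` — the multiplicative
#' amplitude-attenuation model of ERD.
#'
#' @param profile A [subject_profile()].
#' @param label Class index in `1..K`.
#' @param n_channels Number of electrodes.
#' @param duration_s Trial length in seconds (cue at 0, first sample at
#'   `t0_s`).
#' @param fs Sampling rate in Hz; must exceed twice the beta center.
#' @param K Number of classes (defines the valid label range and the
#'   default topography).
#' @param t0_s Time of the first sample relative to the cue (default -0.5).
#' @param seed Integer seed for this trial (default: the profile seed), or
#'   `NULL` to draw from the current RNG stream. Seeds must never be
#'   derived from the label: correlated generator streams would imprint
#'   spurious class information on the noise.
#'
#' @return A `trial` object: list with `data` (channels x time matrix),
#'   `fs`, `label`, `t0_s`.
#' @export
simulate_trial <- function(profile, label, n_channels, duration_s, fs,
                           K = 4L, t0_s = -0.5, seed = profile$seed) {
  stopifnot(inherits(profile, "subject_profile"))
  K <- check_count(K, "K", min = 2L)
  label <- check_label(label, K)
  n_channels <- check_count(n_channels, "n_channels")
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (fs <= 2 * profile$beta_center_hz) {
    abort_arg("`fs` must exceed twice the beta band center (Nyquist).", "fs")
  }
  n <- round(duration_s * fs)
  topo <- profile$channel_topography %||% default_topography(K, n_channels)
  if (length(topo) < K) abort_arg("`channel_topography` must map every class.")
  carriers <- as.integer(topo[[label]])
  if (any(carriers < 1L | carriers > n_channels)) {
    abort_arg("`channel_topography` indexes a channel outside 1..n_channels.")
  }
  t <- t0_s + seq_len(n) / fs - 1 / fs
  post <- t >= 0
  amp <- sqrt(profile$snr / 2)  # split signal power across mu and beta
  draw <- function() {
    m <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      bg <- pink_noise(n, fs)
      mu <- narrowband_noise(n, fs, profile$mu_center_hz)
      be <- narrowband_noise(n, fs, profile$beta_center_hz)
      gain <- rep(1, n)
      if (ch %in% carriers) gain[post] <- 1 - profile$erd_depth
      m[ch, ] <- bg + amp * gain * (mu + be)
    }
    m
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(data = x, fs = fs, label = label, t0_s = t0_s),
            class = "trial")
}

#' Simulate a balanced epoched dataset for one subject
#'
#' Generates `n_trials_per_class` trials per class and shuffles their order
#' with the profile's seed, producing the per-subject collection downstream
#' modules consume.
#'
#' @inheritParams simulate_trial
#' @param n_trials_per_class Trials per class (>= 1).
#' @return An `eeg_epochs` object: list with `data`
#'   (trials x channels x time array), `labels`, `fs`, `t0_s`, `K`,
#'   `subject_id`.
#' @export
simulate_subject <- function(profile, n_trials_per_class, n_channels = 22L,
                             duration_s = 4.5, fs = 250, K = 4L,
                             t0_s = -0.5) {
  stopifnot(inherits(profile, "subject_profile"))
  n_trials_per_class <- check_count(n_trials_per_class, "n_trials_per_class")
  K <- check_count(K, "K", min = 2L)
  n_trials <- n_trials_per_class * K
  n <- round(duration_s * fs)
  data <- array(0, dim = c(n_trials, n_channels, n))
  # One continuous RNG stream for the whole subject, with the label order
  # shuffled before any noise is drawn: the labels influence nothing but
  # the ERD gain, so no class information can leak through the generator.
  labels <- with_seed(derive_seed(profile$seed, "order"),
                      sample(rep(seq_len(K), n_trials_per_class)))
  with_seed(derive_seed(profile$seed, "noise"), {
    for (i in seq_len(n_trials)) {
      tr <- simulate_trial(profile, labels[i], n_channels, duration_s, fs,
                           K = K, t0_s = t0_s, seed = NULL)
      data[i, , ] <- tr$data
    }
  })
  new_eeg_epochs(data, labels, fs = fs, t0_s = t0_s, K = K,
                 subject_id = profile$subject_id)
}

new_eeg_epochs <- function(data, labels, fs, t0_s, K, subject_id) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1L] == length(labels))
  if (any(labels < 1L | labels > K)) abort_arg("labels must lie in 1..K.")
  structure(list(data = data, labels = as.integer(labels), fs = fs,
                 t0_s = t0_s, K = as.integer(K),
                 subject_id = as.character(subject_id)),
            class = "eeg_epochs")
}

#' @export
#' @method print eeg_epochs
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz, K = %d\n",
    x$subject_id, d[1L], d[2L], d[3L], x$fs, x$K))
  invisible(x)
}

#' Simulate a population of experts and illiterates
#'
#' One dataset per profile, all sharing sampling rate, duration, channel
#' count and class count, so that pretraining can rank subjects and split
#' them into a source (expert) and targets (illiterates).
#'
#' @param expert_profile A [subject_profile()] intended as the
#'   high-performing source subject.
#' @param illiterate_profiles List of [subject_profile()]s for the
#'   low-performing targets.
#' @inheritParams simulate_subject
#' @return Named list of `eeg_epochs`, one per subject.
#' @export
make_population <- function(expert_profile, illiterate_profiles,
                            n_trials_per_class = 72L, n_channels = 22L,
                            duration_s = 4.5, fs = 250, K = 4L) {
  profiles <- c(list(expert_profile), illiterate_profiles)
  if (length(profiles) < 2L) abort_arg("need at least 2 profiles.")
  ids <- vapply(profiles, function(p) p$subject_id, character(1L))
  if (anyDuplicated(ids)) abort_arg("duplicate subject_id in population.")
  out <- lapply(profiles, simulate_subject,
                n_trials_per_class = n_trials_per_class,
                n_channels = n_channels, duration_s = duration_s,
                fs = fs, K = K)
  names(out) <- ids
  out
}
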