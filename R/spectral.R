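# Spectral workload pipeline: zero-phase Butterworth band-pass filtering,
# stimulus-locked epoching of correct artifact-free trials, tapered-FFT
# power spectra, band powers, and the theta-Fz / alpha-Pz workload score.

# ---- Butterworth design and zero-phase application -------------------------

# polynomial coefficients (descending powers, leading 1) from roots
poly_from_roots <- function(r) {
  coef <- 1
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# digital Butterworth low-/high-pass via analog prototype + bilinear
# transform, returned as cascaded second-order sections: a narrow high-pass
# (0.1 Hz at 500 Hz) clusters all poles near z = 1 and is numerically
# unusable in direct form, while biquads stay well conditioned
butter_design <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  w <- 2 * fs * tan(pi * fc / fs)                       # prewarped analog cutoff
  k <- seq_len(order)
  p0 <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit-circle LP poles
  p <- if (type == "low") w * p0 else w / p0
  zp <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))          # bilinear poles
  z0 <- if (type == "low") -1 else 1                     # z-plane zeros
  zref <- if (type == "low") 1 else -1                   # unity gain at DC / Nyquist
  # pair complex-conjugate poles into second-order sections
  cplx <- zp[Im(zp) > 1e-12]
  realp <- Re(zp[abs(Im(zp)) <= 1e-12])
  sos <- lapply(cplx, function(pp) {
    a <- Re(poly_from_roots(c(pp, Conj(pp))))
    list(b = c(1, -2 * z0, 1), a = a / a[1])
  })
  if (length(realp)) {
    if (length(realp) %% 2 == 1) {
      sos <- c(sos, list(list(b = c(1, -z0), a = c(1, -realp[1]))))
      realp <- realp[-1]
    }
    while (length(realp)) {
      a <- Re(poly_from_roots(realp[1:2]))
      sos <- c(sos, list(list(b = c(1, -2 * z0, 1), a = a / a[1])))
      realp <- realp[-(1:2)]
    }
  }
  ev <- function(cf) sum(cf * zref^-(seq_along(cf) - 1))
  lapply(sos, function(s) {
    s$b <- s$b * ev(s$a) / ev(s$b)                       # unity gain per section
    s
  })
}

# one direct-form biquad built on stats::filter (C-backed), warm-started at
# the steady state for a constant input x[1] (the equivalent of scipy's
# lfilter_zi) so the slow 0.1 Hz poles are not kicked by a spurious step
iir_apply <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(x[1], nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1) + seq_along(x)]
  if (length(a) > 1) {
    y0 <- x[1] * sum(b) / sum(a)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = rep(y0, length(a) - 1)))
  }
  v
}

sos_apply <- function(sos, x) {
  for (s in sos) x <- iir_apply(s$b, s$a, x)
  x
}

# forward-backward (zero-phase) filtering with odd-reflection edge padding
filtfilt_ba <- function(sos, x, npad) {
  n <- length(x)
  npad <- min(n - 1, npad)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- sos_apply(sos, xp)
  y <- rev(sos_apply(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes each channel's mean, then applies a 4th-order Butterworth
#' high-pass at `low` Hz and a 4th-order Butterworth low-pass at `high` Hz,
#' each forward and backward so the net filter has zero phase. Edge
#' transients are controlled with odd-reflection padding scaled to the
#' high-pass time constant. Events and recording length are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; requires `0 < low < high < rate / 2`.
#' @param order Filter order of each cascade stage.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stopf("invalid band [%g, %g] Hz for sampling rate %g Hz", low, high, fs)
  hp <- butter_design(order, low, fs, "high")
  lp <- butter_design(order, high, fs, "low")
  npad <- ceiling(3 * fs / low)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    x <- x - mean(x)
    x <- filtfilt_ba(hp, x, npad)
    rec$data[i, ] <- filtfilt_ba(lp, x, npad)
  }
  rec
}

# ---- Epoching --------------------------------------------------------------

#' Extract stimulus-locked epochs of correct, artifact-free trials
#'
#' Cuts one fixed-length segment per retained trial, time-locked to the
#' trial's event marker. A trial is retained only if (a) it was answered
#' correctly (omissions count as errors), (b) the whole window lies inside
#' the recording, and (c) the peak-to-peak amplitude on every analysis
#' channel stays below `artifact_threshold`.
#'
#' @param rec An `eeg_recording` (typically already band-pass filtered).
#' @param trials A `trial_log`; every `trial_id` must have an event marker.
#' @param window Numeric `(pre, post)` in seconds relative to stimulus onset;
#'   the default `c(-0.5, 1.5)` yields 2-s epochs.
#' @param artifact_threshold Peak-to-peak rejection threshold in uV.
#' @param channels Analysis channels kept in the epochs (and screened for
#'   artifacts); default Fz and Pz.
#' @return An `eeg_epochs` object: array `[epoch, channel, sample]` plus the
#'   retained `trial_ids`, channel labels, sampling rate and window.
#' @export
extract_epochs <- function(rec, trials, window = c(-0.5, 1.5),
                           artifact_threshold = 150,
                           channels = c("Fz", "Pz")) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[2] > window[1])
  chan_idx <- channel_index(rec, channels)
  ev <- rec$events
  missing <- setdiff(trials$trial_id, ev$trial_id)
  if (length(missing))
    stopf("no event marker for trial_id(s): %s",
          paste(utils::head(missing, 10), collapse = ", "))
  fs <- rec$sampling_rate
  len <- round((window[2] - window[1]) * fs)
  if (len < 2) stopf("epoch window shorter than 2 samples")
  onset_sample <- ev$sample[match(trials$trial_id, ev$trial_id)]
  start <- onset_sample + round(window[1] * fs)          # 0-based
  keep <- trials$correct & !trials$omitted &
    start >= 0 & (start + len) <= n_samples(rec)
  idx <- which(keep)

  data <- array(NA_real_, dim = c(length(idx), length(channels), len),
                dimnames = list(NULL, channels, NULL))
  ok <- rep(TRUE, length(idx))
  for (j in seq_along(idx)) {
    cols <- (start[idx[j]] + 1):(start[idx[j]] + len)
    seg <- rec$data[chan_idx, cols, drop = FALSE]
    pp <- apply(seg, 1, function(v) max(v) - min(v))
    if (any(pp >= artifact_threshold)) ok[j] <- FALSE else data[j, , ] <- seg
  }
  structure(list(data = data[ok, , , drop = FALSE],
                 trial_ids = trials$trial_id[idx][ok],
                 channels = channels, sampling_rate = fs, window = window),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs: %d epochs x %d channels x %d samples @ %g Hz>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate))
  invisible(x)
}

# ---- Spectra ---------------------------------------------------------------

# Hanning-edge ("Tukey") taper: cosine ramps over `r`/2 of the length at each
# edge, flat in between; r = 0.1 reproduces a "10% Hanning window" smoothing.
hanning_taper <- function(n, r = 0.1) {
  w <- rep(1, n)
  L <- floor(r * n / 2)
  if (L > 0) {
    ramp <- sin(pi * (seq_len(L) - 0.5) / (2 * L))^2
    w[seq_len(L)] <- ramp
    w[n + 1 - seq_len(L)] <- ramp
  }
  w
}

#' Power spectrum of one signal segment
#'
#' Removes the mean, applies the taper, zero-pads to the next power of two
#' (1024 points for a 2-s epoch at 500 Hz, giving the 500/1024 = 0.488 Hz
#' bin spacing), and returns the one-sided power spectrum normalized so that
#' (a) the bins of a unit-amplitude in-band sinusoid sum to ~0.5 uV^2 and
#' (b) with `taper = "rect"` the bin sum equals the segment's mean squared
#' amplitude exactly (Parseval).
#'
#' @param x Numeric vector (microvolts), at least 2 samples.
#' @param fs Sampling rate in Hz.
#' @param taper `"hanning10"` (default): Hanning taper over 10% of the
#'   segment, i.e. 5% cosine ramps at each edge; `"rect"`: no taper.
#' @return A `power_spectrum`: list with `freq` (Hz, uniform spacing) and
#'   `power` (uV^2 per bin).
#' @export
power_spectrum <- function(x, fs, taper = c("hanning10", "rect")) {
  taper <- match.arg(taper)
  n <- length(x)
  if (n < 2) stopf("segment shorter than 2 samples")
  w <- if (taper == "rect") rep(1, n) else hanning_taper(n, 0.1)
  xw <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  half <- nfft / 2
  p <- Mod(X[1:(half + 1)])^2 / (nfft * sum(w^2))
  p[2:half] <- 2 * p[2:half]                  # fold negative frequencies
  structure(list(freq = (0:half) * fs / nfft, power = p, fs = fs,
                 nfft = nfft, taper = taper),
            class = "power_spectrum")
}

#' Power spectrum of one epoch and channel
#'
#' @param epochs An `eeg_epochs` object.
#' @param channel Channel label present in the epochs.
#' @param which Epoch index (default 1).
#' @inheritParams power_spectrum
#' @return A `power_spectrum`.
#' @export
epoch_power_spectrum <- function(epochs, channel, which = 1,
                                 taper = c("hanning10", "rect")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stopf("channel '%s' not present in epochs", channel)
  if (which < 1 || which > dim(epochs$data)[1])
    stopf("epoch index %d out of range", which)
  power_spectrum(epochs$data[which, ci, ], epochs$sampling_rate, taper)
}

#' Band power from a power spectrum
#'
#' Sums the power of all bins whose center frequency lies in `[lo, hi)`;
#' the half-open convention means the shared 8 Hz edge of the theta (4-8 Hz)
#' and alpha (8-12 Hz) bands is counted exactly once.
#'
#' @param spectrum A `power_spectrum`.
#' @param band Numeric `(lo, hi)` in Hz with `lo < hi`.
#' @return Band power in uV^2.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"), length(band) == 2)
  if (band[2] <= band[1])
    stopf("empty band [%g, %g): upper edge must exceed lower edge", band[1], band[2])
  sel <- spectrum$freq >= band[1] & spectrum$freq < band[2]
  if (!any(sel))
    stopf("band [%g, %g) contains no spectral bins", band[1], band[2])
  sum(spectrum$power[sel])
}

# ---- Workload score --------------------------------------------------------

#' Compute the theta/alpha brain-workload score (TAR)
#'
#' Computes per-epoch theta-band power at Fz and alpha-band power at Pz,
#' averages the per-epoch band powers, and returns the ratio
#' `TAR = theta_fz / alpha_pz` (ratio of means; `method = "mean_of_ratios"`
#' averages the per-epoch ratios instead). The per-epoch band-power series
#' is kept in the result.
#'
#' @param epochs An `eeg_epochs` containing channels Fz and Pz.
#' @param theta_band,alpha_band Bands in Hz (half-open).
#' @param theta_channel,alpha_channel Channel labels for the two bands.
#' @param method Aggregation across epochs.
#' @param taper Taper passed to [power_spectrum()].
#' @return A `workload_score`: list with `theta_fz`, `alpha_pz`, `tar`,
#'   `n_epochs` and the per-epoch data frame `per_epoch`.
#' @export
compute_tar <- function(epochs, theta_band = c(4, 8), alpha_band = c(8, 12),
                        theta_channel = "Fz", alpha_channel = "Pz",
                        method = c("ratio_of_means", "mean_of_ratios"),
                        taper = "hanning10") {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- dim(epochs$data)[1]
  if (n < 1)
    stopf("insufficient data: no epochs survived selection")
  ti <- match(theta_channel, epochs$channels)
  ai <- match(alpha_channel, epochs$channels)
  if (is.na(ti) || is.na(ai))
    stopf("epochs lack analysis channel(s) %s/%s", theta_channel, alpha_channel)
  fs <- epochs$sampling_rate
  theta <- numeric(n)
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    theta[i] <- band_power(power_spectrum(epochs$data[i, ti, ], fs, taper), theta_band)
    alpha[i] <- band_power(power_spectrum(epochs$data[i, ai, ], fs, taper), alpha_band)
  }
  theta_fz <- mean(theta)
  alpha_pz <- mean(alpha)
  if (alpha_pz <= 0)
    stopf("undefined ratio: alpha band power at %s is zero", alpha_channel)
  tar <- if (method == "ratio_of_means") theta_fz / alpha_pz
         else mean(theta / alpha)
  structure(list(theta_fz = theta_fz, alpha_pz = alpha_pz, tar = tar,
                 n_epochs = n, method = method,
                 per_epoch = data.frame(trial_id = epochs$trial_ids,
                                        theta_fz = theta, alpha_pz = alpha)),
            class = "workload_score")
}

#' @export
print.workload_score <- function(x, ...) {
  cat(sprintf("<workload_score: TAR = %.3f (theta Fz %.3f / alpha Pz %.3f uV^2), %d epochs>\n",
              x$tar, x$theta_fz, x$alpha_pz, x$n_epochs))
  invisible(x)
}

#' Full workload pipeline for one session
#'
#' Band-pass filters the recording, extracts stimulus-locked epochs of the
#' correct artifact-free trials and computes the workload score.
#'
#' @inheritParams extract_epochs
#' @inheritParams compute_tar
#' @param filter_band Band-pass edges in Hz.
#' @return A `workload_score`.
#' @export
session_workload <- function(rec, trials, filter_band = c(0.1, 30),
                             window = c(-0.5, 1.5), artifact_threshold = 150,
                             theta_band = c(4, 8), alpha_band = c(8, 12),
                             method = "ratio_of_means") {
  rec <- bandpass_filter(rec, filter_band[1], filter_band[2])
  ep <- extract_epochs(rec, trials, window, artifact_threshold)
  compute_tar(ep, theta_band, alpha_band, method = method)
}
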