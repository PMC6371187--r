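# Continuous-EEG synthesis: 1/f background noise in every channel, a theta
# oscillation at Fz and an alpha oscillation at Pz whose amplitudes set the
# session's expected theta/alpha ratio, stimulus markers, and occasional
# high-amplitude artifact transients.

# 64-channel actiCap-style 10-20/10-10 montage
MONTAGE_64 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
  "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
  "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
  "P5", "P1", "FCz", "P2", "P6", "PO7", "PO3", "POz", "PO4")

#' Standard electrode montages for the generator
#'
#' `default_montage()` returns 64 scalp channels plus two eye channels
#' (HEOG, VEOG); `small_montage()` is a 4 + 2 channel subset that keeps the
#' analysis channels Fz and Pz and is convenient for fast simulations.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() c(MONTAGE_64, "HEOG", "VEOG")

#' @rdname default_montage
#' @export
small_montage <- function() c("Fz", "Cz", "Pz", "Oz", "HEOG", "VEOG")

#' EEG generator parameters
#'
#' The background in every channel is 1/f ("pink") noise parameterized by
#' its one-sided power spectral density at 1 Hz (`noise_psd1`, uV^2/Hz) and
#' spectral exponent; the density is floored below 0.1 Hz. Fz additionally
#' carries a theta-band sinusoid (default 6 Hz) and Pz an alpha-band
#' sinusoid (default 10 Hz); because the band power of a sinusoid of
#' amplitude A is A^2/2, these amplitudes control the expected theta/alpha
#' ratio analytically. A fraction of trials receives a high-amplitude
#' half-sine transient (default 300 uV over 0.5 s) inside the analysis
#' window, emulating movement artifacts; eye channels carry noise only.
#'
#' @param sampling_rate Hz, default 500; must be at least 64 Hz so the alpha
#'   band is representable.
#' @param channels Channel labels; must contain Fz and Pz.
#' @param theta_amp,alpha_amp Oscillation amplitudes in uV at Fz / Pz.
#' @param theta_freq,alpha_freq Oscillation frequencies in Hz.
#' @param noise_psd1 Noise PSD at 1 Hz in uV^2/Hz (0 disables noise).
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param artifact_prob Per-trial artifact probability.
#' @param artifact_amp,artifact_dur Artifact amplitude (uV) and duration (s).
#' @param eye_channels Labels treated as eye channels (noise only).
#' @return An `eeg_gen_params` list.
#' @export
eeg_gen_params <- function(sampling_rate = 500, channels = default_montage(),
                           theta_amp = 10, alpha_amp = 10,
                           theta_freq = 6, alpha_freq = 10,
                           noise_psd1 = 10, noise_exponent = 1,
                           artifact_prob = 0.05, artifact_amp = 300,
                           artifact_dur = 0.5,
                           eye_channels = c("HEOG", "VEOG")) {
  if (sampling_rate < 64)
    stopf("sampling rate %g Hz is below 64 Hz; the alpha band is unrepresentable",
          sampling_rate)
  if (!all(c("Fz", "Pz") %in% channels))
    stopf("channel set must contain the analysis channels Fz and Pz")
  stopifnot(theta_amp >= 0, alpha_amp >= 0, noise_psd1 >= 0,
            artifact_prob >= 0, artifact_prob <= 1, artifact_amp >= 0)
  structure(list(sampling_rate = sampling_rate, channels = channels,
                 theta_amp = theta_amp, alpha_amp = alpha_amp,
                 theta_freq = theta_freq, alpha_freq = alpha_freq,
                 noise_psd1 = noise_psd1, noise_exponent = noise_exponent,
                 artifact_prob = artifact_prob, artifact_amp = artifact_amp,
                 artifact_dur = artifact_dur,
                 eye_channels = intersect(eye_channels, channels)),
            class = "eeg_gen_params")
}

# Expected 1/f-noise power (uV^2) falling in [lo, hi) Hz: the integral of the
# generator's PSD over the band. Used to compensate oscillation amplitudes so
# the expected measured TAR equals a latent target.
noise_band_power <- function(params, band) {
  lo <- max(band[1], 0.1)
  hi <- band[2]
  if (params$noise_psd1 <= 0 || hi <= lo) return(0)
  a <- params$noise_exponent
  params$noise_psd1 * if (abs(a - 1) < 1e-12) log(hi / lo)
                      else (hi^(1 - a) - lo^(1 - a)) / (1 - a)
}

# Stationary Gaussian noise with one-sided PSD S(f) = psd1 / max(f, 0.1)^a,
# synthesized in the frequency domain at the next power of two and truncated.
synth_pink_noise <- function(n, fs, psd1, exponent) {
  if (psd1 <= 0) return(numeric(n))
  nfft <- 2^ceiling(log2(max(n, 4)))
  df <- fs / nfft
  half <- nfft / 2
  f <- (1:half) * df
  s <- psd1 / pmax(f, 0.1)^exponent
  amp <- sqrt(nfft^2 * s * df / 4)
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * amp
  z[half] <- complex(real = sqrt(2) * Re(z[half]), imaginary = 0)  # Nyquist bin real
  spec <- c(0 + 0i, z[-half], z[half], Conj(rev(z[-half])))
  Re(stats::fft(spec, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Simulate a continuous EEG recording for a simulated session
#'
#' Builds a recording spanning all trials plus padding: each trial
#' contributes a stimulus marker at its onset sample; Fz carries the theta
#' oscillation and Pz the alpha oscillation on top of 1/f noise in all
#' channels; artifact trials (drawn per trial with `artifact_prob`) receive
#' a high-amplitude transient 0.2 s after stimulus onset on all scalp
#' channels. The trial indices that received an artifact are stored in the
#' `"artifact_trials"` attribute.
#'
#' @param trials A `trial_log` (must be strictly ordered in time).
#' @param params An `eeg_gen_params`.
#' @param seed Integer seed.
#' @return An `eeg_recording`.
#' @export
simulate_eeg <- function(trials, params = eeg_gen_params(), seed = 1) {
  stopifnot(inherits(params, "eeg_gen_params"))
  if (params$sampling_rate < 64)
    stopf("sampling rate %g Hz is below 64 Hz; the alpha band is unrepresentable",
          params$sampling_rate)
  onset <- trials$onset
  if (is.unsorted(onset, strictly = TRUE))
    stopf("trials must be strictly ordered in time")
  fs <- params$sampling_rate
  nsamp <- ceiling((max(onset) + 2.0) * fs)
  nchan <- length(params$channels)
  scalp <- setdiff(params$channels, params$eye_channels)

  data <- with_seed(seed, {
    m <- matrix(0, nrow = nchan, ncol = nsamp,
                dimnames = list(params$channels, NULL))
    for (i in seq_len(nchan))
      m[i, ] <- synth_pink_noise(nsamp, fs, params$noise_psd1, params$noise_exponent)
    t <- (seq_len(nsamp) - 1) / fs
    m["Fz", ] <- m["Fz", ] +
      params$theta_amp * sin(2 * pi * params$theta_freq * t + stats::runif(1, 0, 2 * pi))
    m["Pz", ] <- m["Pz", ] +
      params$alpha_amp * sin(2 * pi * params$alpha_freq * t + stats::runif(1, 0, 2 * pi))
    art <- which(stats::runif(length(onset)) < params$artifact_prob)
    if (length(art) && params$artifact_amp > 0) {
      len <- max(2L, round(params$artifact_dur * fs))
      pulse <- params$artifact_amp * sin(pi * (seq_len(len) - 1) / (len - 1))
      for (k in art) {
        s0 <- round((onset[k] + 0.2) * fs) + 1
        idx <- s0:min(s0 + len - 1, nsamp)
        m[scalp, idx] <- sweep(m[scalp, idx, drop = FALSE], 2,
                               pulse[seq_along(idx)], "+")
      }
    }
    attr(m, "artifact_trials") <- art
    m
  })
  art <- attr(data, "artifact_trials")
  attr(data, "artifact_trials") <- NULL
  events <- data.frame(sample = as.integer(round(onset * fs)),
                       trial_id = trials$trial_id, code = "1",
                       stringsAsFactors = FALSE)
  rec <- eeg_recording(data, params$channels, fs, events)
  attr(rec, "artifact_trials") <- trials$trial_id[art]
  rec
}

#' Set oscillation amplitudes for a target theta/alpha ratio
#'
#' Keeps the alpha amplitude fixed and solves for the theta amplitude such
#' that the expected measured ratio (oscillation band power A^2/2 plus the
#' analytic 1/f-noise power in each band) equals `tar_target`.
#'
#' @param tar_target Desired expected TAR (> 0 and large enough that the
#'   required theta power is positive given the noise floor).
#' @param params An `eeg_gen_params`.
#' @param theta_band,alpha_band Analysis bands in Hz.
#' @return `params` with `theta_amp` replaced.
#' @export
amps_for_tar <- function(tar_target, params = eeg_gen_params(),
                         theta_band = c(4, 8), alpha_band = c(8, 12)) {
  if (!is.finite(tar_target) || tar_target <= 0)
    stopf("infeasible TAR target %g: must be positive", tar_target)
  n_th <- noise_band_power(params, theta_band)
  n_al <- noise_band_power(params, alpha_band)
  alpha_pow <- params$alpha_amp^2 / 2 + n_al
  theta_pow <- tar_target * alpha_pow - n_th
  if (theta_pow <= 0)
    stopf("infeasible TAR target %g: below the noise floor %g",
          tar_target, n_th / alpha_pow)
  params$theta_amp <- sqrt(2 * theta_pow)
  params
}
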