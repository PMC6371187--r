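# Independent oracles used by the test suite. These deliberately avoid the
# package's own spectral code paths: band powers come from an explicit DFT
# evaluated bin by bin, Welch estimates from hand-rolled Hann periodograms,
# and regression coefficients from the normal equations.

# band power via an explicit DFT over the band's bins only
oracle_band_power <- function(x, fs, band, taper = c("hanning10", "rect")) {
  taper <- match.arg(taper)
  n <- length(x)
  w <- if (taper == "rect") rep(1, n) else {
    v <- rep(1, n)
    L <- floor(0.1 * n / 2)
    if (L > 0) {
      ramp <- sin(pi * (seq_len(L) - 0.5) / (2 * L))^2
      v[seq_len(L)] <- ramp
      v[n + 1 - seq_len(L)] <- ramp
    }
    v
  }
  xw <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(n))
  freqs <- (0:(nfft / 2)) * fs / nfft
  bins <- which(freqs >= band[1] & freqs < band[2])
  total <- 0
  for (k in bins) {
    m <- k - 1
    ex <- exp(-2i * pi * m * (0:(n - 1)) / nfft)
    Xk <- sum(xw * ex)
    p <- Mod(Xk)^2 / (nfft * sum(w^2))
    if (m != 0 && m != nfft / 2) p <- 2 * p
    total <- total + p
  }
  total
}

# Welch band-power ratio: 2-s Hann segments, 50% overlap, mean periodogram
oracle_welch_ratio <- function(x_fz, x_pz, fs,
                               theta = c(4, 8), alpha = c(8, 12)) {
  seg_len <- 2 * fs
  step <- seg_len / 2
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  bp <- function(x, band) {
    starts <- seq(1, length(x) - seg_len + 1, by = step)
    freqs <- (0:(seg_len / 2)) * fs / seg_len
    bins <- which(freqs >= band[1] & freqs < band[2])
    ps <- sapply(starts, function(s) {
      seg <- x[s:(s + seg_len - 1)]
      X <- fft((seg - mean(seg)) * hann)
      p <- Mod(X[1:(seg_len / 2 + 1)])^2 / (seg_len * sum(hann^2))
      p[2:(seg_len / 2)] <- 2 * p[2:(seg_len / 2)]
      sum(p[bins])
    })
    mean(ps)
  }
  bp(x_fz, theta) / bp(x_pz, alpha)
}

# least squares through the normal equations
oracle_lsq <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(beta = drop(beta), se = se, df = df)
}

# design + behavior for a quick synthetic Stroop session
quick_stroop_session <- function(seed, error_prob = 0, omission_prob = 0,
                                 tar = 2, noise_psd1 = 0, artifact_prob = 0,
                                 channels = c("Fz", "Pz")) {
  design <- build_stroop_design(seed, "congruent")
  model <- behavior_model("stroop", error_prob = error_prob,
                          omission_prob = omission_prob)
  trials <- simulate_behavior(design, model, seed = seed + 1)
  params <- eeg_gen_params(channels = channels, noise_psd1 = noise_psd1,
                           artifact_prob = artifact_prob,
                           eye_channels = character())
  params <- amps_for_tar(tar, params)
  rec <- simulate_eeg(trials, params, seed = seed + 2)
  list(design = design, trials = trials, rec = rec, params = params)
}

# tiny latent study configuration for fast cohort tests
small_latent_config <- function(seed = 1, ...) {
  study_config(n_simulator = 6, n_attention = 5, n_control = 5, seed = seed, ...)
}
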