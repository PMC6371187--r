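# Spectral pipeline: filter response, epoch extraction and rejection,
# tapered-FFT normalization against analytic and DFT oracles, band-power
# semantics and the TAR score's invariances.

fs <- 500

test_that("band-pass preserves in-band amplitude and rejects DC and 50 Hz", {
  t <- (0:(60 * fs - 1)) / fs
  mk <- function(x) eeg_recording(matrix(x, nrow = 1), "Fz", fs)
  mid <- (10 * fs):(50 * fs)    # away from the filter's edge transients
  y10 <- bandpass_filter(mk(sin(2 * pi * 10 * t)))$data[1, ]
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.01)
  y50 <- bandpass_filter(mk(sin(2 * pi * 50 * t)))$data[1, ]
  expect_lt(max(abs(y50[mid])), 0.1)   # >= 90% attenuation at 50 Hz
  ydc <- bandpass_filter(mk(rep(100, length(t))))$data[1, ]
  expect_equal(mean(ydc), 0, tolerance = 1e-6)
  # length and events untouched
  rec <- mk(sin(2 * pi * 10 * t))
  expect_equal(ncol(bandpass_filter(rec)$data), length(t))
  expect_error(bandpass_filter(rec, 30, 0.1), "invalid band")
  expect_error(bandpass_filter(rec, 0.1, 300), "invalid band")
})

test_that("epochs are 2 s (1000 samples at 500 Hz), correct-trial only", {
  sess <- quick_stroop_session(61)
  rec <- bandpass_filter(sess$rec)
  ep <- extract_epochs(rec, sess$trials)
  expect_equal(dim(ep$data)[1], nrow(sess$trials))  # no rejection case
  expect_equal(dim(ep$data)[3], 1000)
  expect_equal(ep$sampling_rate * diff(ep$window), 1000)
  # only correct trials are epoched
  trials <- sess$trials
  trials$correct[5:10] <- FALSE
  ep2 <- extract_epochs(rec, trials)
  expect_equal(dim(ep2$data)[1], nrow(trials) - 6)
  expect_false(any(5:10 %in% ep2$trial_ids))
  # unknown trial marker is a consistency error
  trials2 <- sess$trials
  trials2$trial_id[1] <- 9999L
  expect_error(extract_epochs(rec, trials2), "9999")
})

test_that("injected artifact trials are exactly the ones rejected", {
  sess <- quick_stroop_session(71, tar = 1, artifact_prob = 0.05)
  art <- attr(sess$rec, "artifact_trials")
  expect_gt(length(art), 0)
  ep <- extract_epochs(bandpass_filter(sess$rec), sess$trials,
                       artifact_threshold = 150)
  expect_setequal(setdiff(sess$trials$trial_id, ep$trial_ids), art)
})

test_that("2-s epochs at 500 Hz give the 0.488 Hz bin spacing", {
  x <- sin(2 * pi * 6 * (0:999) / fs)
  sp <- power_spectrum(x, fs)
  expect_equal(sp$freq[2] - sp$freq[1], 500 / 1024)
  expect_equal(round(sp$freq[2], 3), 0.488)
  expect_equal(sp$nfft, 1024)
  # uniform spacing, non-negative power
  expect_equal(diff(sp$freq), rep(500 / 1024, length(sp$freq) - 1))
  expect_true(all(sp$power >= 0))
})

test_that("spectrum normalization matches the analytic sinusoid power", {
  t2 <- (0:999) / fs
  sp <- power_spectrum(sin(2 * pi * 6 * t2), fs)
  expect_equal(band_power(sp, c(4, 8)), 0.5, tolerance = 0.02)   # A^2/2
  expect_lt(band_power(sp, c(8, 12)), 0.005)
  expect_lt(band_power(sp, c(13, 30)), 0.005)
  # all-zero epoch: all bins zero
  expect_true(all(power_spectrum(rep(0, 1000), fs)$power == 0))
  expect_error(power_spectrum(c(1), fs), "2 samples")
})

test_that("Parseval holds exactly for the untapered variant", {
  set.seed(8)
  for (n in c(777, 1000, 1024)) {
    x <- rnorm(n)
    sp <- power_spectrum(x, fs, taper = "rect")
    ms <- mean((x - mean(x))^2)
    expect_equal(sum(sp$power), ms, tolerance = 1e-6)
  }
})

test_that("tapered band powers agree with the explicit-DFT oracle to 1e-6", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(1000, sd = 10) + 5 * sin(2 * pi * runif(1, 2, 20) * (0:999) / fs)
    sp <- power_spectrum(x, fs)
    for (band in list(c(4, 8), c(8, 12))) {
      expect_equal(band_power(sp, band), oracle_band_power(x, fs, band),
                   tolerance = 1e-6)
    }
  }
})

test_that("band_power sums bins additively and rejects degenerate bands", {
  sp <- power_spectrum(rnorm(1000), fs)
  flat <- sp
  flat$power <- rep(1, length(sp$power))
  k <- sum(flat$freq >= 4 & flat$freq < 8)
  expect_equal(band_power(flat, c(4, 8)), k)
  # half-open bands: theta + alpha counts the 8 Hz edge exactly once
  expect_equal(band_power(flat, c(4, 8)) + band_power(flat, c(8, 12)),
               sum(flat$freq >= 4 & flat$freq < 12))
  expect_error(band_power(sp, c(8, 8)), "empty band")
})

make_epochs <- function(theta_amp, alpha_amp, n_ep = 4, scale = 1) {
  t2 <- (0:999) / fs
  data <- array(0, dim = c(n_ep, 2, 1000), dimnames = list(NULL, c("Fz", "Pz"), NULL))
  for (i in seq_len(n_ep)) {
    data[i, 1, ] <- scale * theta_amp * sin(2 * pi * 6 * t2 + i)
    data[i, 2, ] <- scale * alpha_amp * sin(2 * pi * 10 * t2 + i)
  }
  structure(list(data = data, trial_ids = seq_len(n_ep),
                 channels = c("Fz", "Pz"), sampling_rate = fs,
                 window = c(-0.5, 1.5)), class = "eeg_epochs")
}

test_that("TAR is scale invariant and monotone in the band amplitudes", {
  base <- compute_tar(make_epochs(2, 2))
  expect_equal(base$tar, 1, tolerance = 0.01)
  expect_equal(base$n_epochs, 4)
  scaled <- compute_tar(make_epochs(2, 2, scale = 7))
  expect_equal(scaled$tar, base$tar, tolerance = 1e-9)
  # monotonicity
  up_theta <- sapply(c(1, 2, 3, 4), function(a) compute_tar(make_epochs(a, 2))$tar)
  expect_true(all(diff(up_theta) > 0))
  up_alpha <- sapply(c(1, 2, 3, 4), function(a) compute_tar(make_epochs(2, a))$tar)
  expect_true(all(diff(up_alpha) < 0))
  # theta amplitude sqrt(2) times alpha => power ratio 2
  expect_equal(compute_tar(make_epochs(2 * sqrt(2), 2))$tar, 2, tolerance = 0.01)
})

test_that("mean-of-ratios option and error paths of compute_tar work", {
  ep <- make_epochs(2, 2)
  expect_equal(compute_tar(ep, method = "mean_of_ratios")$tar, 1,
               tolerance = 0.01)
  zero <- make_epochs(1, 0)
  expect_error(compute_tar(zero), "alpha band power")
  empty <- make_epochs(1, 1, n_ep = 1)
  empty$data <- empty$data[0, , , drop = FALSE]
  empty$trial_ids <- integer()
  expect_error(compute_tar(empty), "insufficient")
})
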