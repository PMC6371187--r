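# Behavioral and EEG generators: degenerate rates, Monte-Carlo recovery of
# configured RT parameters, determinism, latent-TAR recovery, artifact
# plumbing, and the cohort-level structure of simulate_study.

test_that("zero error and omission rates give all-correct, time-ordered trials", {
  d <- build_stroop_design(4, "congruent")
  tl <- simulate_behavior(d, behavior_model("stroop", error_prob = 0,
                                            omission_prob = 0), seed = 1)
  expect_true(all(tl$correct))
  expect_false(any(tl$omitted))
  expect_identical(tl$response, tl$correct_response)
  expect_true(all(diff(tl$onset) > 0))
  expect_true(all(tl$rt <= tl$response_window))
  expect_true(all(tl$rt > 0))
})

test_that("simulated RT means recover the configured condition means", {
  # 10,000 trials per condition via repeated sessions; sample means must fall
  # within 2 SE of the configured 0.905 / 1.078 s
  model <- behavior_model("stroop", error_prob = 0, omission_prob = 0)
  rts <- list(congruent = numeric(), incongruent = numeric())
  k <- 0
  while (length(rts$congruent) < 10000) {
    k <- k + 1
    tl <- simulate_behavior(build_stroop_design(k, "congruent"), model, seed = 100 + k)
    for (cc in names(rts)) rts[[cc]] <- c(rts[[cc]], tl$rt[tl$condition == cc])
  }
  for (cc in names(rts)) {
    x <- rts[[cc]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - model$mean_rt[[cc]]), 2 * se + 0.002)
  }
})

test_that("behavior simulation is deterministic under a fixed seed", {
  d <- build_flanker_design(6)
  a <- simulate_behavior(d, seed = 5)
  b <- simulate_behavior(d, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_behavior(d, seed = 6)
  expect_false(identical(a$rt, c$rt))
})

test_that("missing condition parameters raise a configuration error naming it", {
  d <- build_stroop_design(1, "congruent")
  bad <- behavior_model("stroop")
  bad$mean_rt <- bad$mean_rt["congruent"]
  expect_error(simulate_behavior(d, bad), "incongruent")
})

test_that("simulate_eeg places markers, honors symmetry and rejects low rates", {
  sess <- quick_stroop_session(21, tar = 1)
  expect_equal(nrow(sess$rec$events), nrow(sess$trials))
  expect_equal(sess$rec$events$sample,
               as.integer(round(sess$trials$onset * 500)))
  # equal theta and alpha amplitude => TAR ~ 1 by symmetric construction
  ws <- session_workload(sess$rec, sess$trials)
  expect_equal(ws$tar, 1, tolerance = 0.05)
  expect_error(eeg_gen_params(sampling_rate = 50), "64 Hz")
})

test_that("theta power at twice alpha power yields TAR ~ 2 (Welch oracle)", {
  sess <- quick_stroop_session(31, tar = 2)
  ws <- session_workload(sess$rec, sess$trials)
  expect_equal(ws$tar, 2, tolerance = 0.05)
  # independent Welch periodogram on the raw (unfiltered) signal
  fz <- sess$rec$data[1, ]
  pz <- sess$rec$data[2, ]
  expect_equal(oracle_welch_ratio(fz, pz, 500), 2, tolerance = 0.1)
})

test_that("artifact probability one drives epoch retention to zero", {
  sess <- quick_stroop_session(41, tar = 1, artifact_prob = 1)
  rec <- bandpass_filter(sess$rec)
  ep <- extract_epochs(rec, sess$trials)
  expect_equal(dim(ep$data)[1], 0)
  expect_error(compute_tar(ep), "insufficient")
})

test_that("infeasible TAR targets are rejected with a message", {
  p <- eeg_gen_params(channels = c("Fz", "Pz"), noise_psd1 = 10)
  expect_error(amps_for_tar(0.01, p), "infeasible")
  expect_error(amps_for_tar(-1, p), "infeasible")
})

test_that("latent cohorts have the right shape and reproducibility", {
  cfg <- small_latent_config(seed = 7)
  co <- simulate_study(cfg, signals = "latent")
  expect_equal(nrow(co$subjects), 16)
  expect_equal(length(co$sessions), 16 * 2 * 3)
  co2 <- simulate_study(cfg, signals = "latent")
  expect_identical(cohort_workload(co), cohort_workload(co2))
  # subject independence: same master seed, so identical subject seeds; a
  # subject's draws depend only on its own seed
  wl <- cohort_workload(co)
  expect_true(all(wl$tar > 0))
})

test_that("full group sizes give 76 subjects and 152 sessions per task", {
  co <- simulate_study(study_config(seed = 3, tasks = "stroop"),
                       signals = "latent")
  expect_equal(nrow(co$subjects), 76)
  expect_equal(as.vector(table(co$subjects$group)[c("simulator", "attention", "control")]),
               c(30L, 23L, 23L))
  wl <- cohort_workload(co)
  expect_equal(nrow(wl), 152)  # 76 subjects x 2 phases
})

test_that("latent pre-post correlation approaches the configured r", {
  # large-sample check of the moment-matched bivariate lognormal draw
  x <- brainload:::with_seed(11, brainload:::draw_latent_tar(
    50000, 2.06, 1.41, 1.34, 0.67, 0.7))
  expect_equal(cor(x[, "pre"], x[, "post"]), 0.7, tolerance = 0.05)
  expect_equal(mean(x[, "pre"]), 2.06, tolerance = 0.03)
  expect_equal(sd(x[, "pre"]), 1.41, tolerance = 0.05)
  expect_equal(mean(x[, "post"]), 1.34, tolerance = 0.02)
  expect_equal(sd(x[, "post"]), 0.67, tolerance = 0.05)
  # cohort-level draws inherit the structure (noisier at n = 600)
  cfg <- study_config(n_simulator = 600, n_attention = 2, n_control = 2,
                      seed = 11, tasks = "stroop", r = 0.7)
  g <- compute_gains(cohort_workload(simulate_study(cfg, signals = "latent")),
                     "tar")
  g <- g[g$group == "simulator", ]
  expect_equal(cor(g$pre, g$post), 0.7, tolerance = 0.2)
  expect_equal(mean(g$pre), 2.06, tolerance = 0.15)
})

test_that("simulator-group mean Stroop TAR drop is ~0.72 across seeds", {
  drops <- sapply(1:25, function(s) {
    co <- simulate_study(study_config(n_simulator = 30, n_attention = 2,
                                      n_control = 2, seed = s,
                                      tasks = "stroop"), signals = "latent")
    g <- compute_gains(cohort_workload(co), "tar")
    -mean(g$gain[g$group == "simulator"])
  })
  # configured drop 2.06 - 1.34 = 0.72; Monte-Carlo error of the mean of 25
  # cohort means of 30 subjects each is ~0.033
  expect_equal(mean(drops), 0.72, tolerance = 0.1)
})

test_that("changing one subject's seed leaves the others' data unchanged", {
  cfg <- small_latent_config(seed = 5)
  co <- simulate_study(cfg, signals = "latent")
  # rebuild subject 3 with a different seed by hand
  subj <- co$subjects[3, ]
  subj$seed <- subj$seed + 1L
  sess_new <- brainload:::simulate_subject(subj, cfg, "latent")
  sess_old <- brainload:::simulate_subject(co$subjects[3, ], cfg, "latent")
  expect_false(identical(sess_new[[1]]$latent_tar, sess_old[[1]]$latent_tar))
  # other subjects are generated from their own seeds only
  sess_4 <- brainload:::simulate_subject(co$subjects[4, ], cfg, "latent")
  key <- names(sess_4)[1]
  expect_identical(sess_4[[key]]$latent_tar, co$sessions[[key]]$latent_tar)
})

test_that("waveform cohorts carry trial logs and recordings that analyze end to end", {
  cfg <- study_config(n_simulator = 2, n_attention = 2, n_control = 2,
                      seed = 13, tasks = "stroop",
                      eeg = eeg_gen_params(channels = small_montage()))
  co <- simulate_study(cfg, signals = "eeg")
  expect_equal(length(co$sessions), 12)
  s <- co$sessions[[1]]
  expect_s3_class(s$recording, "eeg_recording")
  wl <- cohort_workload(co)
  expect_true(all(wl$n_epochs > 200))
  # measured TAR tracks the latent targets cohort-wide
  lat <- cohort_workload(co, source = "latent")
  expect_equal(wl$tar, lat$tar, tolerance = 0.1)
})
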