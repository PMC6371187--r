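# Baseline ANOVA, planned orthogonal contrasts and the repeated-measures
# effect size, all cross-checked against brute-force oracles.

grp762323 <- rep(c("simulator", "attention", "control"), c(30, 23, 23))

test_that("baseline ANOVA matches brute-force sums of squares", {
  set.seed(5)
  values <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2))
  groups <- rep(c("a", "b", "c"), each = 10)
  r <- baseline_anova(values, groups)
  # brute-force decomposition
  gm <- tapply(values, groups, mean)
  ssb <- sum(10 * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  expect_equal(r$F, (ssb / 2) / (ssw / 27), tolerance = 1e-12)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 27)
  # equal group means -> F = 0
  r0 <- baseline_anova(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(r0$F, 0)
  # degenerate variance and tiny groups are rejected
  expect_error(baseline_anova(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               "zero within-group variance")
  expect_error(baseline_anova(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("planned contrasts match a normal-equations oracle", {
  set.seed(6)
  gains <- data.frame(group = rep(c("simulator", "attention", "control"),
                                  c(2, 2, 2)),
                      gain = c(-2, -2, 0, 0, 1, 1) + rnorm(6, sd = 1e-3))
  ct <- planned_contrast_regression(gains)
  X <- cbind(1,
             c(1, 1, 1, 1, -2, -2),
             c(1, 1, -1, -1, 0, 0))
  o <- oracle_lsq(X, gains$gain)
  expect_equal(ct$B, o$beta[2:3], tolerance = 1e-9)
  expect_equal(ct$SE, unname(o$se[2:3]), tolerance = 1e-9)
  expect_equal(ct$df, rep(o$df, 2))
  expect_equal(ct$F, (ct$B / ct$SE)^2, tolerance = 1e-9)
})

test_that("unequal group sizes keep the integer weights and match the oracle", {
  set.seed(7)
  gains <- data.frame(group = grp762323, gain = rnorm(76))
  ct <- planned_contrast_regression(gains)
  codes <- brainload:::contrast_codes(gains$group)
  X <- cbind(1, codes$c1, codes$c2)
  o <- oracle_lsq(X, gains$gain)
  expect_equal(ct$B, o$beta[2:3], tolerance = 1e-10)
  expect_equal(ct$SE, unname(o$se[2:3]), tolerance = 1e-10)
  expect_equal(ct$df, c(73, 73))          # n - 3 for n = 76
  # equal sizes: the code vectors are orthogonal
  eq <- brainload:::contrast_codes(rep(c("simulator", "attention", "control"), 10))
  expect_equal(sum(eq$c1 * eq$c2), 0)
})

test_that("one-tailed p values follow the hypothesized direction", {
  gains <- data.frame(group = grp762323,
                      gain = c(rep(-1, 30), rep(0, 23), rep(0.5, 23)))
  gains$gain <- gains$gain + rnorm(76, sd = 0.3)
  ct <- planned_contrast_regression(gains, alternative = "less")
  expect_true(all(ct$B < 0))
  expect_true(all(ct$p < 0.05))
  flip <- gains
  flip$gain <- -flip$gain
  ctf <- planned_contrast_regression(flip, alternative = "less")
  expect_true(all(ctf$p > 0.5))
  # degenerate all-equal gains: zero coefficients, p = 0.5
  flat <- data.frame(group = grp762323, gain = rep(2, 76))
  ct0 <- planned_contrast_regression(flat)
  expect_equal(ct0$B, c(0, 0))
  expect_equal(ct0$p, c(0.5, 0.5))
  # missing group
  expect_error(planned_contrast_regression(
    data.frame(group = rep(c("simulator", "attention"), 5), gain = rnorm(10))),
    "empty group.*control")
})

test_that("type-I error of the one-tailed contrast is calibrated (quick check)", {
  set.seed(11)
  rej <- replicate(400, {
    ct <- planned_contrast_regression(data.frame(group = grp762323,
                                                 gain = rnorm(76)))
    ct$p[ct$contrast == "AxB"] < 0.05
  })
  expect_gte(mean(rej), 0.025)   # full-size calibration runs in acceptance
  expect_lte(mean(rej), 0.075)
})

test_that("morris_deshon_d matches identities and an independent sweep", {
  expect_equal(morris_deshon_d(1.5, 1.5, 1, 1, 0.7)$d, 0)
  # equal SDs with r = 0.5 collapse to (m_pre - m_post) / s
  expect_equal(morris_deshon_d(2, 1.4, 0.8, 0.8, 0.5)$d, 0.6 / 0.8,
               tolerance = 1e-12)
  # sign follows m_pre - m_post
  expect_lt(morris_deshon_d(1.0, 1.6, 0.8, 0.8, 0.5)$d, 0)
  # independent re-implementation over an r sweep for published-style inputs
  ds <- sapply(seq(0.05, 0.95, by = 0.05), function(r) {
    denom <- sqrt(1.41^2 + 0.67^2 - 2 * r * 1.41 * 0.67)
    ((2.06 - 1.34) * sqrt(2 * (1 - r))) / denom
  })
  got <- sapply(seq(0.05, 0.95, by = 0.05), function(r)
    morris_deshon_d(2.06, 1.34, 1.41, 0.67, r)$d)
  expect_equal(got, ds, tolerance = 1e-12)
  # the r ~ 0.65-0.70 region brackets a d of 0.54 for these inputs
  expect_true(min(got[13:14]) < 0.54 && 0.54 < max(got[13:14]) + 0.02)
  # error paths
  expect_error(morris_deshon_d(1, 2, 1, 1, 1), "r must lie")
  expect_error(morris_deshon_d(1, 2, 1, 1, 1 - 1e-16), "undefined")
})

test_that("build_report produces the three tables and handles edge cases", {
  co <- simulate_study(small_latent_config(seed = 21), signals = "latent")
  wl <- cohort_workload(co)
  bh <- cohort_behavior(co)
  rep <- build_report(wl, bh)
  expect_s3_class(rep, "study_report")
  expect_equal(nrow(rep$table2), 2 * 2 * 3)  # 2 outcomes x 3 tasks x 2 contrasts
  expect_equal(nrow(rep$figure3), 3 * 3 * 2)
  expect_true(all(c("B", "SE", "beta", "F", "df", "p", "sig") %in% names(rep$table2)))
  # report means reproduce the configured population cells within MC error
  big <- simulate_study(study_config(n_simulator = 400, n_attention = 2,
                                     n_control = 2, seed = 31, tasks = "stroop"),
                        signals = "latent")
  wlb <- cohort_workload(big)
  sim_pre <- wlb$tar[wlb$group == "simulator" & wlb$phase == "pre"]
  expect_equal(mean(sim_pre), 2.06, tolerance = 0.15)
  # single group: contrast table suppressed with a warning
  expect_warning(r1 <- build_report(wl[wl$group == "simulator", ]),
                 "suppressed")
  expect_null(r1$table2)
  # empty cohort errors
  expect_error(build_report(wl[0, ]), "empty cohort")
  # missing cells produce NA plus warnings
  wl2 <- wl[!(wl$group == "control" & wl$phase == "post" & wl$task == "stroop"), ]
  w <- testthat::capture_warnings(r2 <- build_report(wl2))
  expect_true(any(grepl("missing cell", w)))
  expect_true(any(is.na(r2$table2$p)))
})
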