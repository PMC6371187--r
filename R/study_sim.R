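# Cohort simulation: three groups (driving-simulator training, attention
# training, waiting control), pre and post sessions of all three inhibition
# tasks, with per-group population parameters for the latent theta/alpha
# ratio and for the behavioral RT cells.

# Population TAR mean (SD) per group x task x phase
DEFAULT_TAR_TABLE <- local({
  g <- rep(GROUPS, each = 6)
  t <- rep(rep(TASKS, each = 2), 3)
  p <- rep(c("pre", "post"), 9)
  m <- c(2.06, 1.34, 2.01, 1.27, 1.96, 1.14,    # simulator
         2.03, 2.06, 1.61, 1.44, 1.36, 1.31,    # attention
         1.41, 1.40, 1.57, 1.58, 1.43, 1.43)    # control
  s <- c(1.41, 0.67, 1.23, 0.57, 1.03, 0.80,
         1.65, 1.52, 1.28, 0.70, 0.84, 0.86,
         0.73, 0.98, 1.71, 1.00, 1.28, 1.00)
  data.frame(group = g, task = t, phase = p, mean = m, sd = s,
             stringsAsFactors = FALSE)
})

# Population mean RT (s) per group x task x condition x phase
DEFAULT_RT_TABLE <- local({
  row <- function(task, condition, pre_s, post_s, pre_a, post_a, pre_c, post_c)
    data.frame(group = rep(GROUPS, each = 2), task = task, condition = condition,
               phase = rep(c("pre", "post"), 3),
               mean = c(pre_s, post_s, pre_a, post_a, pre_c, post_c),
               stringsAsFactors = FALSE)
  rbind(
    row("stroop", "congruent",    0.899, 0.853, 0.926, 0.850, 0.893, 0.864),
    row("stroop", "incongruent",  1.060, 0.969, 1.101, 0.995, 1.079, 1.028),
    row("np", "control",          0.660, 0.648, 0.664, 0.651, 0.696, 0.681),
    row("np", "np",               0.675, 0.668, 0.683, 0.668, 0.710, 0.698),
    row("flanker", "compatible",  0.626, 0.586, 0.612, 0.593, 0.623, 0.591),
    row("flanker", "incompatible", 0.825, 0.722, 0.834, 0.751, 0.849, 0.737))
})

# Between-subject SDs (s) of the general-speed intercept and of the
# inhibition-effect slope, derived from the published between-subject RT SDs
# assuming a 0.8 between-condition correlation (see the methods vignette).
DEFAULT_SUBJECT_SD <- c(stroop = 0.12, np = 0.07, flanker = 0.09)
DEFAULT_SLOPE_SD <- c(stroop = 0.12, np = 0.05, flanker = 0.19)

#' Study configuration for the cohort generator
#'
#' Defaults reproduce the stated world of the emulated study: group sizes
#' 30/23/23 (the 76 participants entering the EEG analysis), the published
#' group x task x phase TAR population means and SDs, the published RT cell
#' means, and a pre-post correlation of `r = 0.7`. Latent TAR values are
#' drawn from a bivariate lognormal moment-matched to the configured
#' mean/SD, with the log-scale correlation chosen so that the raw-scale
#' pre-post correlation equals `r`.
#'
#' @param n_simulator,n_attention,n_control Group sizes (each >= 2).
#' @param tar_table Data frame `group, task, phase, mean, sd` of TAR
#'   population parameters.
#' @param rt_table Data frame `group, task, condition, phase, mean` of RT
#'   cell means (s).
#' @param r Pre-post correlation in (-1, 1), applied to latent TARs and to
#'   the behavioral subject effects.
#' @param subject_sd,slope_sd Named per-task SDs (s) of the subject
#'   general-speed intercept and inhibition-effect slope.
#' @param error_prob,omission_prob Flat response error/omission
#'   probabilities used for all conditions (`NULL` keeps each task's
#'   published per-condition error rates, see [behavior_model()]).
#' @param eeg An [eeg_gen_params()] object used for every session.
#' @param tasks Tasks to simulate.
#' @param seed Master seed; all randomness derives from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_simulator = 30, n_attention = 23, n_control = 23,
                         tar_table = DEFAULT_TAR_TABLE,
                         rt_table = DEFAULT_RT_TABLE,
                         r = 0.7,
                         subject_sd = DEFAULT_SUBJECT_SD,
                         slope_sd = DEFAULT_SLOPE_SD,
                         error_prob = NULL, omission_prob = 0.005,
                         eeg = eeg_gen_params(), tasks = TASKS, seed = 1) {
  sizes <- c(simulator = n_simulator, attention = n_attention, control = n_control)
  if (any(sizes < 2)) stopf("every group needs at least 2 subjects")
  if (!(r > -1 && r < 1)) stopf("r must lie in (-1, 1), got %g", r)
  stopifnot(all(tar_table$sd > 0), all(tar_table$mean > 0))
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  structure(list(sizes = sizes, tar_table = tar_table, rt_table = rt_table,
                 r = r, subject_sd = subject_sd, slope_sd = slope_sd,
                 error_prob = error_prob, omission_prob = omission_prob,
                 eeg = eeg, tasks = tasks, seed = seed),
            class = "study_config")
}

# log-scale correlation of a bivariate lognormal that yields raw correlation
# rho for log-sds s1, s2
lnorm_log_corr <- function(rho, s1, s2) {
  val <- log(1 + rho * sqrt(expm1(s1^2) * expm1(s2^2))) / (s1 * s2)
  max(-0.999, min(0.999, val))
}

# draw n correlated (pre, post) pairs from a moment-matched bivariate lognormal
draw_latent_tar <- function(n, m_pre, s_pre, m_post, s_post, r) {
  p1 <- lnorm_params(m_pre, s_pre)
  p2 <- lnorm_params(m_post, s_post)
  rl <- lnorm_log_corr(r, p1$sdlog, p2$sdlog)
  z1 <- stats::rnorm(n)
  z2 <- rl * z1 + sqrt(1 - rl^2) * stats::rnorm(n)
  cbind(pre = exp(p1$meanlog + p1$sdlog * z1),
        post = exp(p2$meanlog + p2$sdlog * z2))
}

# draw n correlated (pre, post) pairs from a zero-mean bivariate normal
draw_bvn <- function(n, sd, r) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(pre = sd * z1, post = sd * z2)
}

lookup <- function(tbl, col, ...) {
  sel <- rep(TRUE, nrow(tbl))
  for (kv in list(...)) sel <- sel & tbl[[kv[1]]] == kv[2]
  if (sum(sel) != 1) stopf("table lookup did not match exactly one row")
  tbl[[col]][sel]
}

#' Simulate a full three-group pre/post cohort
#'
#' For every subject, draws latent pre/post TAR targets per task from the
#' group's bivariate distribution and subject-level behavioral effects, then
#' simulates the pre and post sessions of each task. With
#' `signals = "eeg"` every session carries a trial log and a continuous EEG
#' recording whose oscillation amplitudes are set (noise-compensated) so the
#' pipeline's expected TAR equals the latent target. With
#' `signals = "latent"` no waveforms or trial-level logs are synthesized:
#' each session records the latent TAR and summary-level behavioral means
#' (the same population model, aggregated analytically), which is orders of
#' magnitude faster and statistically equivalent for the gain analysis.
#'
#' The starting block alternates between the pre and post phase of each
#' subject, and subjects' random streams are independent: changing one
#' subject's seed leaves all other subjects' data unchanged.
#'
#' @param config A [study_config()].
#' @param signals `"eeg"` (full waveforms) or `"latent"`.
#' @param verbose Print progress.
#' @return A `cohort`: list with `subjects` (data frame: subject, group,
#'   seed), `sessions` (list of per subject x phase x task records) and the
#'   config.
#' @export
simulate_study <- function(config = study_config(), signals = c("eeg", "latent"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  signals <- match.arg(signals)
  sizes <- config$sizes
  n_total <- sum(sizes)
  group <- rep(names(sizes), sizes)
  subj_seed <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1, n_total))
  subjects <- data.frame(subject = sprintf("s%03d", seq_len(n_total)),
                         group = group, seed = subj_seed,
                         start_index = rep_len(1:2, n_total),
                         stringsAsFactors = FALSE)

  sessions <- list()
  for (i in seq_len(n_total)) {
    if (verbose) message(sprintf("subject %d/%d (%s)", i, n_total, group[i]))
    sessions <- c(sessions,
                  simulate_subject(subjects[i, ], config, signals))
  }
  structure(list(subjects = subjects, sessions = sessions,
                 signals = signals, config = config),
            class = "cohort")
}

# trials per condition in one session, used for the analytic summary mode
CONDITION_TRIALS <- c(stroop = 144, np = 112, flanker = 144)

simulate_subject <- function(subj, config, signals) {
  out <- list()
  for (task in config$tasks) {
    lat <- with_seed(derive_seed(subj$seed, task, "latent"), {
      tar <- draw_latent_tar(1,
        lookup(config$tar_table, "mean", c("group", subj$group), c("task", task), c("phase", "pre")),
        lookup(config$tar_table, "sd",   c("group", subj$group), c("task", task), c("phase", "pre")),
        lookup(config$tar_table, "mean", c("group", subj$group), c("task", task), c("phase", "post")),
        lookup(config$tar_table, "sd",   c("group", subj$group), c("task", task), c("phase", "post")),
        config$r)
      list(tar = tar,
           u = draw_bvn(1, config$subject_sd[[task]], config$r),
           v = draw_bvn(1, config$slope_sd[[task]], config$r))
    })
    for (phase in c("pre", "post")) {
      key <- sprintf("%s_%s_%s", subj$subject, phase, task)
      tar_target <- lat$tar[1, phase]
      conds <- task_conditions(task)
      inhib <- inhibition_condition(task)
      cell <- vapply(conds, function(cc)
        lookup(config$rt_table, "mean", c("group", subj$group), c("task", task),
               c("condition", cc), c("phase", phase)), numeric(1))
      mean_rt <- cell + lat$u[1, phase] + (conds == inhib) * lat$v[1, phase]
      mean_rt <- pmax(mean_rt, 0.15)   # keep RT means physiologically positive
      names(mean_rt) <- conds

      rec <- NULL; trial_log <- NULL; rt_means <- NULL; n_epochs <- NA_integer_
      if (signals == "eeg") {
        start_index <- if (phase == "pre") subj$start_index else 3 - subj$start_index
        design <- build_design(task, derive_seed(subj$seed, phase, task, "design"),
                               start_index)
        model <- behavior_model(task, mean_rt = mean_rt,
                                error_prob = config$error_prob,
                                omission_prob = config$omission_prob)
        trial_log <- simulate_behavior(design, model,
                                       derive_seed(subj$seed, phase, task, "behavior"))
        params <- amps_for_tar(tar_target, config$eeg)
        rec <- simulate_eeg(trial_log, params,
                            derive_seed(subj$seed, phase, task, "eeg"))
      } else {
        # summary-level draw: condition means of correct trials, with the
        # trial-sampling error of averaging ~n/2 correct RTs per condition
        err <- config$error_prob %||% behavior_model(task)$error_prob
        if (length(err) == 1) err <- stats::setNames(rep(err, 2), conds)
        n_corr <- pmax(2, round(CONDITION_TRIALS[[task]] *
                                  (1 - err[conds] - config$omission_prob)))
        sd_trial <- 0.25 * mean_rt
        rt_means <- with_seed(derive_seed(subj$seed, phase, task, "summary"),
                              stats::rnorm(length(conds), mean_rt,
                                           sd_trial / sqrt(n_corr)))
        names(rt_means) <- conds
      }
      out[[key]] <- list(subject = subj$subject, group = subj$group,
                         phase = phase, task = task,
                         latent_tar = unname(tar_target),
                         trial_log = trial_log, recording = rec,
                         rt_means = rt_means)
    }
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects (%s), %d sessions, signals = '%s'>\n",
              nrow(x$subjects),
              paste(sprintf("%s %d", names(x$config$sizes), x$config$sizes),
                    collapse = ", "),
              length(x$sessions), x$signals))
  invisible(x)
}

#' Per-session workload table of a cohort
#'
#' For a waveform cohort, runs the full spectral pipeline
#' ([session_workload()]) on every session; for a latent cohort, reports the
#' latent TAR targets directly.
#'
#' @param cohort A `cohort`.
#' @param source `"auto"` (pipeline for waveform cohorts, latent otherwise),
#'   `"eeg"`, or `"latent"`.
#' @param ... Passed to [session_workload()].
#' @return Data frame: subject, group, phase, task, theta_fz, alpha_pz, tar,
#'   n_epochs.
#' @export
cohort_workload <- function(cohort, source = c("auto", "eeg", "latent"), ...) {
  source <- match.arg(source)
  if (source == "auto") source <- if (cohort$signals == "eeg") "eeg" else "latent"
  rows <- lapply(cohort$sessions, function(s) {
    if (source == "eeg") {
      if (is.null(s$recording))
        stopf("session %s_%s_%s has no recording (latent cohort?)",
              s$subject, s$phase, s$task)
      ws <- session_workload(s$recording, s$trial_log, ...)
      data.frame(subject = s$subject, group = s$group, phase = s$phase,
                 task = s$task, theta_fz = ws$theta_fz, alpha_pz = ws$alpha_pz,
                 tar = ws$tar, n_epochs = ws$n_epochs, stringsAsFactors = FALSE)
    } else {
      data.frame(subject = s$subject, group = s$group, phase = s$phase,
                 task = s$task, theta_fz = NA_real_, alpha_pz = NA_real_,
                 tar = s$latent_tar, n_epochs = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-session behavior table of a cohort
#'
#' @param cohort A `cohort`.
#' @return Data frame: subject, group, phase, task, rt_neutral,
#'   rt_inhibition, inhibition_score (plus error counts for waveform
#'   cohorts).
#' @export
cohort_behavior <- function(cohort) {
  rows <- lapply(cohort$sessions, function(s) {
    base <- data.frame(subject = s$subject, group = s$group, phase = s$phase,
                       task = s$task, stringsAsFactors = FALSE)
    if (!is.null(s$trial_log)) {
      cbind(base, as.data.frame(summarize_behavior(s$trial_log))[
        , c("rt_neutral", "rt_inhibition", "err_neutral", "err_inhibition",
            "inhibition_score")])
    } else {
      conds <- task_conditions(s$task)
      inhib <- inhibition_condition(s$task)
      neutral <- setdiff(conds, inhib)
      cbind(base, data.frame(rt_neutral = unname(s$rt_means[neutral]),
                             rt_inhibition = unname(s$rt_means[inhib]),
                             err_neutral = NA_real_, err_inhibition = NA_real_,
                             inhibition_score = unname(s$rt_means[inhib] -
                                                         s$rt_means[neutral])))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as a directory tree
#'
#' Layout: `subject-XXX/phase-{pre,post}/task-{stroop,np,flanker}/` holding
#' `trials.csv` and the native EEG container (`eeg.dat/.json/.events.csv`),
#' plus a top-level `manifest.json` with group labels and seeds. Latent
#' cohorts store a `sessions.csv` summary instead of per-session files.
#'
#' @param cohort A `cohort`.
#' @param dir Target directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the
#'   `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "brainload-cohort", version = 1L,
                   signals = cohort$signals, seed = cohort$config$seed,
                   r = cohort$config$r,
                   sizes = as.list(cohort$config$sizes),
                   tasks = cohort$config$tasks,
                   subjects = cohort$subjects)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  lat <- data.frame(subject = vapply(cohort$sessions, `[[`, "", "subject"),
                    group = vapply(cohort$sessions, `[[`, "", "group"),
                    phase = vapply(cohort$sessions, `[[`, "", "phase"),
                    task = vapply(cohort$sessions, `[[`, "", "task"),
                    latent_tar = vapply(cohort$sessions, `[[`, 0, "latent_tar"),
                    stringsAsFactors = FALSE)
  if (cohort$signals == "latent") {
    beh <- cohort_behavior(cohort)
    lat <- cbind(lat, beh[, c("rt_neutral", "rt_inhibition", "inhibition_score")])
  }
  utils::write.csv(lat, file.path(dir, "sessions.csv"), row.names = FALSE)
  if (cohort$signals == "eeg") {
    for (s in cohort$sessions) {
      sdir <- file.path(dir, paste0("subject-", sub("^s", "", s$subject)),
                        paste0("phase-", s$phase), paste0("task-", s$task))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_trial_log(s$trial_log, file.path(sdir, "trials.csv"))
      write_recording(s$recording, file.path(sdir, "eeg"))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopf("no manifest.json in '%s'", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  subjects <- as.data.frame(manifest$subjects)
  sess_tab <- utils::read.csv(file.path(dir, "sessions.csv"),
                              stringsAsFactors = FALSE)
  sessions <- list()
  missing <- character()
  for (i in seq_len(nrow(sess_tab))) {
    s <- as.list(sess_tab[i, ])
    key <- sprintf("%s_%s_%s", s$subject, s$phase, s$task)
    if (identical(manifest$signals, "eeg")) {
      sdir <- file.path(dir, paste0("subject-", sub("^s", "", s$subject)),
                        paste0("phase-", s$phase), paste0("task-", s$task))
      tpath <- file.path(sdir, "trials.csv")
      if (!file.exists(tpath) || !file.exists(file.path(sdir, "eeg.dat"))) {
        missing <- c(missing, sdir)
        next
      }
      s$trial_log <- read_trial_log(tpath)
      s$recording <- read_recording(file.path(sdir, "eeg"))
    } else {
      s$rt_means <- NULL
      if (!is.null(sess_tab$rt_neutral)) {
        conds <- task_conditions(s$task)
        inhib <- inhibition_condition(s$task)
        rt <- c(sess_tab$rt_neutral[i], sess_tab$rt_inhibition[i])
        names(rt) <- c(setdiff(conds, inhib), inhib)
        s$rt_means <- rt
      }
    }
    sessions[[key]] <- s
  }
  if (length(missing))
    stopf("partial cohort: missing session files under:\n  %s",
          paste(missing, collapse = "\n  "))
  structure(list(subjects = subjects, sessions = sessions,
                 signals = manifest$signals,
                 config = list(seed = manifest$seed, r = manifest$r,
                               sizes = unlist(manifest$sizes),
                               tasks = unlist(manifest$tasks))),
            class = "cohort")
}
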