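# Behavioral response simulation: per-condition reaction-time distributions,
# button errors and omissions, plus the session timeline (stimulus onsets).

#' Behavioral response model for one task
#'
#' Defaults reproduce the pre-training (T1) condition effects of the study
#' the generator emulates: mean RTs 0.905/1.078 s (Stroop congruent vs
#' incongruent), 0.671/0.688 s (negative priming control vs priming) and
#' 0.622/0.835 s (flanker compatible vs incompatible); per-condition error
#' probabilities derive from the printed T1 error counts over the per-session
#' condition trial counts (e.g. 2.3/144 and 5.6/144 for Stroop). RTs are
#' drawn from a lognormal moment-matched to (mean, sd) and truncated at the
#' trial's response window; omitted responses count as errors downstream.
#' The default trial-to-trial RT sd is 25% of the condition mean, a typical
#' within-subject coefficient of variation for speeded two-choice RT.
#'
#' @param task `"stroop"`, `"np"` or `"flanker"`.
#' @param mean_rt Named numeric, mean RT (s) per condition.
#' @param sd_rt Named numeric, trial RT sd (s) per condition.
#' @param error_prob Named numeric in `[0, 1]`, wrong-button probability per
#'   condition (a single unnamed value is recycled to both conditions).
#' @param omission_prob Probability in `[0, 1]` of no response at all.
#' @return A `behavior_model` list.
#' @export
behavior_model <- function(task, mean_rt = NULL, sd_rt = NULL,
                           error_prob = NULL, omission_prob = 0.005) {
  task <- match.arg(task, TASKS)
  conds <- task_conditions(task)
  def_mean <- switch(task,
    stroop  = c(congruent = 0.905, incongruent = 1.078),
    np      = c(control = 0.671, np = 0.688),
    flanker = c(compatible = 0.622, incompatible = 0.835))
  def_err <- switch(task,
    stroop  = c(congruent = 2.3 / 144, incongruent = 5.6 / 144),
    np      = c(control = 5.9 / 112, np = 7.1 / 112),
    flanker = c(compatible = 0.9 / 144, incompatible = 2.9 / 144))
  mean_rt <- mean_rt %||% def_mean
  sd_rt <- sd_rt %||% (0.25 * mean_rt)
  error_prob <- error_prob %||% def_err
  if (is.null(names(error_prob)) && length(error_prob) == 1)
    error_prob <- stats::setNames(rep(error_prob, 2), conds)
  if (is.null(names(sd_rt)) && length(sd_rt) == 1)
    sd_rt <- stats::setNames(rep(sd_rt, 2), conds)
  stopifnot(all(mean_rt > 0), all(sd_rt > 0),
            all(error_prob >= 0 & error_prob <= 1),
            omission_prob >= 0, omission_prob <= 1)
  structure(list(task = task, conditions = conds, mean_rt = mean_rt,
                 sd_rt = sd_rt, error_prob = error_prob,
                 omission_prob = omission_prob, buttons = task_buttons(task)),
            class = "behavior_model")
}

# session timing constants (s): lead-in before the first fixation and the
# pause between blocks; both give the epoching window room at the edges
SESSION_LEAD_IN <- 1.0
BLOCK_GAP <- 5.0

#' Simulate behavioral responses for a task design
#'
#' Draws one response per trial: RT from the condition's truncated lognormal,
#' a wrong button with the condition's error probability, or no response with
#' the omission probability (omissions are counted as errors). Stimulus
#' onsets accumulate fixation, response and inter-trial intervals, so trials
#' are strictly ordered in time; the first onset starts 1 s into the session
#' and blocks are separated by a 5 s pause.
#'
#' @param design A `task_design`.
#' @param model A `behavior_model` covering the design's conditions
#'   (default: `behavior_model(task)` with its built-in parameters).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return A `trial_log`: the design plus columns `trial_id`, `response`,
#'   `rt` (s, `NA` if omitted), `correct`, `omitted`, `onset` (s).
#' @export
simulate_behavior <- function(design, model = NULL, seed = 1) {
  stopifnot(inherits(design, "task_design"))
  task <- attr(design, "task")
  model <- model %||% behavior_model(task)
  if (!identical(model$task, task))
    stopf("behavior model is for task '%s', design is '%s'", model$task, task)
  missing <- setdiff(unique(design$condition),
                     Reduce(intersect, list(names(model$mean_rt), names(model$sd_rt),
                                            names(model$error_prob))))
  if (length(missing))
    stopf("behavior model lacks parameters for condition(s): %s",
          paste(missing, collapse = ", "))

  n <- nrow(design)
  cond <- design$condition
  rw <- design$response_window
  out <- with_seed(seed, {
    lp <- lnorm_params(model$mean_rt[cond], model$sd_rt[cond])
    fmax <- stats::plnorm(rw, lp$meanlog, lp$sdlog)
    rt <- stats::qlnorm(stats::runif(n) * fmax, lp$meanlog, lp$sdlog)
    omitted <- stats::runif(n) < model$omission_prob
    wrong <- !omitted & stats::runif(n) < model$error_prob[cond]
    response <- design$correct_response
    if (any(wrong)) {
      response[wrong] <- vapply(design$correct_response[wrong], function(cr)
        sample(setdiff(model$buttons, cr), 1), character(1))
    }
    response[omitted] <- NA_character_
    rt[omitted] <- NA_real_
    list(rt = rt, omitted = omitted, wrong = wrong, response = response)
  })

  occupied <- if (task == "np") design$stimulus_duration + design$iti_post
              else ifelse(out$omitted, rw, out$rt)
  new_block <- c(0, as.integer(diff(design$block_index) != 0))
  onset <- SESSION_LEAD_IN + BLOCK_GAP * cumsum(new_block) +
    cumsum(design$fixation_duration) + cumsum(c(0, utils::head(occupied, -1)))

  log <- as.data.frame(design)
  log$trial_id <- seq_len(n)
  log$response <- out$response
  log$rt <- out$rt
  log$correct <- !out$omitted & !out$wrong
  log$omitted <- out$omitted
  log$onset <- onset
  structure(log, class = c("trial_log", "data.frame"),
            task = task, seed = seed)
}

#' Write / read a trial log
#'
#' @param log A `trial_log`.
#' @param path CSV file path.
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task=%s", attr(log, "task") %||% log$task[1]), con)
  utils::write.csv(as.data.frame(log), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
                        colClasses = c(stimulus = "character"))
  structure(df, class = c("trial_log", "data.frame"), task = df$task[1])
}
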