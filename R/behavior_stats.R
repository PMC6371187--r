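# Behavioral summaries: per-condition mean RTs over correct trials, error
# counts (omissions included), and the inhibition difference score.

# inhibition (slow) condition per task; the other condition is neutral
inhibition_condition <- function(task) {
  c(stroop = "incongruent", np = "np", flanker = "incompatible")[[task]]
}

#' Summarize the behavior of one session
#'
#' Mean RTs are computed over correct trials only; omissions and wrong
#' buttons both count as errors. The inhibition score is the mean RT of the
#' inhibition condition minus the mean RT of the neutral condition
#' (incongruent - congruent, priming - control, incompatible - compatible).
#'
#' @param trials A `trial_log` from one subject/phase/task.
#' @return A one-row `behavior_summary` data frame with the two condition
#'   names, mean RTs, error counts, trial counts and `inhibition_score` (s).
#' @export
summarize_behavior <- function(trials) {
  task <- attr(trials, "task") %||% trials$task[1]
  conds <- task_conditions(task)          # (neutral, inhibition)
  inhib <- inhibition_condition(task)
  neutral <- setdiff(conds, inhib)
  stat <- function(cond) {
    sel <- trials$condition == cond
    ok <- sel & trials$correct & !trials$omitted
    if (!any(ok))
      stopf("insufficient data: no correct trials in condition '%s'", cond)
    list(rt = mean(trials$rt[ok]), err = sum(sel) - sum(ok), n = sum(sel))
  }
  sn <- stat(neutral)
  si <- stat(inhib)
  structure(data.frame(task = task,
                       neutral_condition = neutral, inhibition_condition = inhib,
                       rt_neutral = sn$rt, rt_inhibition = si$rt,
                       err_neutral = sn$err, err_inhibition = si$err,
                       n_neutral = sn$n, n_inhibition = si$n,
                       inhibition_score = si$rt - sn$rt,
                       stringsAsFactors = FALSE),
            class = c("behavior_summary", "data.frame"))
}

#' Paired t test on per-subject means
#'
#' Classic paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1` and a two-sided p value, where `d = values_a - values_b`.
#' When every paired difference is exactly zero the statistic is defined as
#' `t = 0, p = 1`; any other zero-variance difference vector is an error.
#'
#' @param values_a,values_b Numeric vectors of equal length `n >= 2`,
#'   paired by subject.
#' @return List with `t`, `df`, `p`.
#' @export
paired_effect_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stopf("paired vectors differ in length (%d vs %d)",
          length(values_a), length(values_b))
  n <- length(values_a)
  if (n < 2) stopf("need at least 2 pairs, got %d", n)
  d <- values_a - values_b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    stopf("zero variance of paired differences: t statistic undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
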