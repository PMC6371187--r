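# Planned-contrast statistics for three-group pre/post training gains:
# baseline one-way ANOVA, joint regression on two orthogonal contrast codes
# with one-tailed directional tests, and the repeated-measures Cohen's d
# corrected for the dependence between pre and post means.

# planned orthogonal contrast codes: C1 both trainings vs control,
# C2 simulator vs attention training
contrast_codes <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), GROUPS)
  if (length(bad))
    stopf("unknown group label(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(GROUPS, collapse = "/"))
  data.frame(
    c1 = c(simulator = 1, attention = 1, control = -2)[group],
    c2 = c(simulator = 1, attention = -1, control = 0)[group])
}

#' Baseline one-way ANOVA
#'
#' Standard one-way decomposition of pre-test values across groups, used to
#' verify that groups do not differ before training.
#'
#' @param values Numeric vector of per-subject pre-test values.
#' @param groups Group labels, same length as `values`; at least two groups
#'   with at least two subjects each.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
baseline_anova <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stopf("need at least 2 groups, got %d", length(sizes))
  if (any(sizes < 2))
    stopf("group(s) with fewer than 2 subjects: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- length(sizes)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(sizes * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  if (ss_within <= 0)
    stopf("zero within-group variance: F statistic undefined")
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = f, df_between = k - 1, df_within = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Planned orthogonal-contrast regression of training gains
#'
#' Regresses per-subject pre-post gains jointly on the two planned contrast
#' codes (with intercept): C1 codes both training groups against the control
#' group (+1, +1, -2) and C2 codes the simulator against the attention
#' training (+1, -1, 0). For each contrast the unstandardized coefficient B,
#' its SE, the standardized coefficient beta, `F = t^2` with `(1, n - 3)`
#' degrees of freedom and a one-tailed p value in the hypothesized direction
#' are reported. The default direction `"less"` encodes the hypothesis that
#' training *reduces* the outcome (gains more negative for trainings than
#' control, and for simulator than attention training).
#'
#' The stated integer weights are used as-is also under unequal group sizes
#' (classic planned-contrast convention). When the gains carry no signal at
#' all (zero residual variance and zero coefficients) the contrasts are
#' reported as `B = 0, F = 0, p = 0.5` rather than dividing by zero.
#'
#' @param gains Data frame with columns `group` (simulator/attention/control)
#'   and `gain` (post minus pre), one row per subject.
#' @param alternative `"less"` (default), `"greater"`, or `"two.sided"`.
#' @return A `contrast_table` data frame with rows `ABxC` and `AxB` and
#'   columns `B`, `SE`, `beta`, `F`, `df`, `p`.
#' @export
planned_contrast_regression <- function(gains, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(gains), all(c("group", "gain") %in% names(gains)))
  present <- GROUPS %in% unique(as.character(gains$group))
  if (!all(present))
    stopf("empty group(s): %s", paste(GROUPS[!present], collapse = ", "))
  n <- nrow(gains)
  if (n < 4) stopf("need at least 4 subjects for df = n - 3 > 0, got %d", n)
  codes <- contrast_codes(gains$group)
  fit <- stats::lm(gains$gain ~ codes$c1 + codes$c2)
  sm <- summary(fit)
  df <- n - 3
  cf <- stats::coef(fit)[-1]
  sigma <- sm$sigma
  sd_y <- stats::sd(gains$gain)
  res <- lapply(1:2, function(j) {
    b <- unname(cf[j])
    if (!is.finite(sigma) || sigma < 1e-12 * max(1, abs(b), sd_y)) {
      # degenerate: all gains (essentially) equal; no signal, no blow-up
      return(data.frame(B = 0, SE = 0, beta = 0, F = 0, df = df, p = 0.5))
    }
    se <- sm$coefficients[j + 1, "Std. Error"]
    t <- b / se
    p <- switch(alternative,
                less = stats::pt(t, df),
                greater = stats::pt(t, df, lower.tail = FALSE),
                two.sided = 2 * stats::pt(-abs(t), df))
    beta <- if (sd_y > 0) b * stats::sd(codes[[j]]) / sd_y else 0
    data.frame(B = b, SE = se, beta = beta, F = t^2, df = df, p = p)
  })
  out <- do.call(rbind, res)
  out <- cbind(contrast = c("ABxC", "AxB"), out)
  rownames(out) <- NULL
  structure(out, class = c("contrast_table", "data.frame"))
}

#' Repeated-measures Cohen's d corrected for dependence between means
#'
#' Standardizes the pre-post change against the standard deviation of the
#' change score and rescales it to the independent-groups metric:
#' `d = (M_pre - M_post) * sqrt(2 * (1 - r)) /
#'      sqrt(SD_pre^2 + SD_post^2 - 2 * r * SD_pre * SD_post)`.
#' For equal SDs and `r = 0.5` this collapses to the familiar
#' `(M_pre - M_post) / SD`. The pre-post correlation `r` is a population
#' quantity that raw summary tables rarely print; it defaults to 0.7.
#'
#' @param m_pre,m_post Pre- and post-test means.
#' @param sd_pre,sd_post Pre- and post-test standard deviations (> 0).
#' @param r Pre-post correlation in (-1, 1).
#' @return An `effect_size` list with `d` and its components.
#' @export
morris_deshon_d <- function(m_pre, m_post, sd_pre, sd_post, r = 0.7) {
  stopifnot(sd_pre > 0, sd_post > 0)
  if (!(r > -1 && r < 1)) stopf("r must lie in (-1, 1), got %g", r)
  denom2 <- sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post
  if (denom2 <= .Machine$double.eps * (sd_pre^2 + sd_post^2))
    stopf("undefined effect size: change-score variance is zero (r = %g with equal SDs)", r)
  d <- (m_pre - m_post) * sqrt(2 * (1 - r)) / sqrt(denom2)
  structure(list(d = d, m_pre = m_pre, m_post = m_post,
                 sd_pre = sd_pre, sd_post = sd_post, r = r),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size: d = %.3f (pre %.3f (%.3f), post %.3f (%.3f), r = %.2f)>\n",
              x$d, x$m_pre, x$sd_pre, x$m_post, x$sd_post, x$r))
  invisible(x)
}

#' Pre-post gains from a long per-session table
#'
#' @param df Data frame with columns `subject`, `group`, `task`, `phase`
#'   (`"pre"`/`"post"`) and the outcome column `outcome`.
#' @param outcome Name of the outcome column (e.g. `"tar"`,
#'   `"inhibition_score"`).
#' @return Data frame with one row per subject x task: `subject`, `group`,
#'   `task`, `pre`, `post`, `gain` (post - pre).
#' @export
compute_gains <- function(df, outcome) {
  stopifnot(outcome %in% names(df))
  pre <- df[df$phase == "pre", ]
  post <- df[df$phase == "post", ]
  key <- function(d) paste(d$subject, d$task)
  m <- match(key(pre), key(post))
  out <- data.frame(subject = pre$subject, group = pre$group, task = pre$task,
                    pre = pre[[outcome]], post = post[[outcome]][m],
                    stringsAsFactors = FALSE)
  out$gain <- out$post - out$pre
  out
}
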