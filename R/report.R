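# Report tables: descriptive group x phase table with repeated-measures
# effect sizes, planned-contrast table per task and outcome, and the
# per-task group means underlying the pre/post change figure.

sig_marker <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ifelse(p < 0.10, "+", "")))
}

#' Build the study report tables
#'
#' From the per-session workload and behavior tables, builds (1) a
#' descriptive table of mean (SD) per group x phase for every measure, with
#' dependence-corrected Cohen's d for the workload rows; (2) a
#' planned-contrast table (B, SE, beta, F, df, one-tailed p, significance
#' markers) per task for the TAR and the behavioral inhibition score; and
#' (3) a figure-data table of per-task pre/post group mean TARs with
#' standard errors.
#'
#' @param workload Data frame from [cohort_workload()] (columns subject,
#'   group, phase, task, tar).
#' @param behavior Optional data frame from [cohort_behavior()].
#' @param r Pre-post correlation used for the effect sizes.
#' @param alternative Direction of the planned contrasts (see
#'   [planned_contrast_regression()]).
#' @return A `study_report` list with `table1`, `table2`, `figure3`.
#' @export
build_report <- function(workload, behavior = NULL, r = 0.7,
                         alternative = "less") {
  if (is.null(workload) || nrow(workload) == 0)
    stopf("empty cohort: no workload rows to report")
  groups_present <- intersect(GROUPS, unique(as.character(workload$group)))

  cell <- function(df, value, task, g, ph) {
    v <- df[[value]][df$task == task & df$group == g & df$phase == ph]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warnf("missing cell: %s / %s / %s", task, g, ph)
      return(list(m = NA_real_, s = NA_real_, n = 0L))
    }
    list(m = mean(v), s = stats::sd(v), n = length(v))
  }

  # ---- Table 1: descriptives -----------------------------------------------
  rows <- list()
  measures <- list()
  if (!is.null(behavior) && nrow(behavior)) {
    for (task in intersect(TASKS, unique(behavior$task))) {
      measures <- c(measures,
                    list(list(df = behavior, task = task, value = "rt_neutral",
                              label = sprintf("%s: RT %s trials (s)", task,
                                              setdiff(task_conditions(task),
                                                      inhibition_condition(task))),
                              d = FALSE),
                         list(df = behavior, task = task, value = "rt_inhibition",
                              label = sprintf("%s: RT %s trials (s)", task,
                                              inhibition_condition(task)),
                              d = FALSE)))
    }
  }
  for (task in intersect(TASKS, unique(workload$task)))
    measures <- c(measures, list(list(df = workload, task = task, value = "tar",
                                      label = sprintf("workload (TAR): %s", task),
                                      d = TRUE)))
  for (ms in measures) {
    row <- data.frame(measure = ms$label, stringsAsFactors = FALSE)
    for (g in groups_present) {
      pre <- cell(ms$df, ms$value, ms$task, g, "pre")
      post <- cell(ms$df, ms$value, ms$task, g, "post")
      row[[paste0(g, "_pre")]] <- sprintf("%.3f (%.3f)", pre$m, pre$s)
      row[[paste0(g, "_post")]] <- sprintf("%.3f (%.3f)", post$m, post$s)
      row[[paste0(g, "_d")]] <-
        if (ms$d && is.finite(pre$m) && is.finite(post$m) && pre$s > 0 && post$s > 0)
          round(morris_deshon_d(pre$m, post$m, pre$s, post$s, r)$d, 2)
        else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  table1 <- do.call(rbind, rows)

  # ---- Table 2: planned contrasts ------------------------------------------
  table2 <- NULL
  if (length(groups_present) < 3) {
    warnf("contrast table suppressed: only %d group(s) present",
          length(groups_present))
  } else {
    outcome_tabs <- list(list(df = workload, value = "tar", label = "workload"))
    if (!is.null(behavior) && nrow(behavior))
      outcome_tabs <- c(outcome_tabs,
                        list(list(df = behavior, value = "inhibition_score",
                                  label = "inhibition score")))
    t2 <- list()
    for (ot in outcome_tabs) {
      for (task in intersect(TASKS, unique(ot$df$task))) {
        gains <- compute_gains(ot$df[ot$df$task == task, ], ot$value)
        gains <- gains[is.finite(gains$gain), ]
        ct <- tryCatch(
          as.data.frame(planned_contrast_regression(gains,
                                                    alternative = alternative)),
          error = function(e) {
            warnf("contrasts unavailable for %s / %s: %s", ot$label, task,
                  conditionMessage(e))
            data.frame(contrast = c("ABxC", "AxB"), B = NA_real_, SE = NA_real_,
                       beta = NA_real_, F = NA_real_, df = NA_integer_,
                       p = NA_real_)
          })
        ct <- cbind(outcome = ot$label, task = task, ct)
        ct$sig <- ifelse(is.na(ct$p), "", sig_marker(ct$p))
        t2[[length(t2) + 1]] <- ct
      }
    }
    table2 <- do.call(rbind, t2)
    rownames(table2) <- NULL
  }

  # ---- Figure data: group means with SEs -----------------------------------
  f3 <- list()
  for (task in intersect(TASKS, unique(workload$task))) {
    for (g in groups_present) {
      for (ph in c("pre", "post")) {
        cc <- cell(workload, "tar", task, g, ph)
        f3[[length(f3) + 1]] <- data.frame(task = task, group = g, phase = ph,
                                           mean_tar = cc$m,
                                           se = if (cc$n > 1) cc$s / sqrt(cc$n) else NA_real_,
                                           n = cc$n, stringsAsFactors = FALSE)
      }
    }
  }
  figure3 <- do.call(rbind, f3)
  structure(list(table1 = table1, table2 = table2, figure3 = figure3, r = r),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Descriptives (mean (SD) per group and phase) ==\n")
  print(x$table1, row.names = FALSE)
  if (!is.null(x$table2)) {
    cat("\n== Planned contrasts (one-tailed) ==\n")
    t2 <- x$table2
    t2$B <- round(t2$B, 3); t2$SE <- round(t2$SE, 3)
    t2$beta <- round(t2$beta, 3); t2$F <- round(t2$F, 2); t2$p <- round(t2$p, 4)
    print(t2, row.names = FALSE)
  }
  invisible(x)
}

#' Write report tables as CSV files
#'
#' Writes `table1.csv`, `table2.csv` (if present) and `figure3_data.csv`
#' into `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table1, file.path(dir, "table1.csv"), row.names = FALSE)
  if (!is.null(report$table2))
    utils::write.csv(report$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(report$figure3, file.path(dir, "figure3_data.csv"),
                   row.names = FALSE)
  invisible(dir)
}
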