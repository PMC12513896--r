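#' Gate participants on task accuracy
#'
#' Participants with strictly less than `threshold` correct responses
#' (successful catches) are excluded from all analyses: such low
#' performance on a straightforward task indicates poor overall task
#' commitment. A participant exactly at the threshold is kept.
#'
#' @param accuracy Named numeric vector of per-participant accuracies in
#'   `[0, 1]`, or a data frame with columns `participant` and `accuracy`.
#' @param threshold Accuracy threshold (default 0.70).
#' @return A list with `kept` and `dropped` data frames (`participant`,
#'   `accuracy`).
#' @export
gate_participants <- function(accuracy, threshold = 0.70) {
  df <- if (is.data.frame(accuracy)) accuracy
  else data.frame(participant = names(accuracy), accuracy = unname(accuracy))
  if (any(df$accuracy < 0 | df$accuracy > 1))
    mf_stop("accuracies must lie in [0, 1]", "mf_parameter_error")
  drop <- df$accuracy < threshold
  list(kept = df[!drop, , drop = FALSE], dropped = df[drop, , drop = FALSE])
}

#' Trial-level filters
#'
#' A trial is dropped when a mouse click occurred before the target-word
#' onset (`early_click`) or when the whole trial — from the start of the
#' animation routine to its end — took strictly longer than `max_trial_s`
#' seconds (`slow_trial`), indicating problematic timing on that trial.
#' Both thresholds are strict as stated: a click exactly at onset and a
#' trial of exactly `max_trial_s` are kept.
#'
#' @param meta A data frame with columns `click_time_s`, `target_onset_s`
#'   and `end_time_s` (e.g. the `meta` from [preprocess_logs()]), or a
#'   single `mf_trial_log`.
#' @param max_trial_s Maximum trial duration (default 5.2 s).
#' @return For a data frame: a character vector per trial, `"keep"`,
#'   `"early_click"` or `"slow_trial"`. For a single log: one such value.
#' @export
filter_trials <- function(meta, max_trial_s = 5.2) {
  if (inherits(meta, "mf_trial_log"))
    meta <- data.frame(click_time_s = meta$click_time_s,
                       target_onset_s = meta$config$target_onset_s,
                       end_time_s = meta$end_time_s)
  early <- !is.na(meta$click_time_s) & meta$click_time_s < meta$target_onset_s
  slow <- meta$end_time_s > max_trial_s
  ifelse(early, "early_click", ifelse(slow, "slow_trial", "keep"))
}

#' Trim reaction times on model residuals
#'
#' Fits an intercept-only linear mixed model with crossed participant and
#' item random intercepts to the reaction times and removes observations
#' whose standardized residual exceeds 3 in absolute value, yielding
#' roughly normally distributed reaction times. If the crossed fit fails,
#' the function falls back to grand-mean standardization and records the
#' fallback.
#'
#' @param rt_table A data frame with columns `participant`, `item_id` and
#'   the reaction-time column.
#' @param rt_col Name of the reaction-time column (default `"rt_s"`).
#' @param cutoff Absolute standardized-residual cutoff (default 3).
#' @return A list: `data` (trimmed table), `n_removed`, and `method`
#'   (`"crossed_lmm"` or `"grand_mean"`).
#' @export
trim_reaction_times <- function(rt_table, rt_col = "rt_s", cutoff = 3) {
  if (is.null(rt_table) || nrow(rt_table) == 0L)
    mf_stop("empty reaction-time table", "mf_screening_error")
  y <- rt_table[[rt_col]]
  stopifnot(!anyNA(y))
  z <- NULL
  method <- "crossed_lmm"
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 1 + (1 | participant) + (1 | item_id),
                 data = cbind(rt_table, y = y), REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (!is.null(fit)) {
    z <- resid(fit) / sigma(fit)
  } else {
    method <- "grand_mean"
    z <- (y - mean(y)) / sd(y)
  }
  z[!is.finite(z)] <- 0  # degenerate: zero residual variance
  drop <- abs(z) > cutoff
  list(data = rt_table[!drop, , drop = FALSE], n_removed = sum(drop),
       method = method)
}

#' Screen a decision table in the canonical order
#'
#' Applies the screening cascade in order: (1) participant accuracy gate,
#' (2) trial-level early-click and slow-trial filters, (3) accounting of
#' trials lost to decision-time extraction because the cursor was always on
#' the target. Returns the surviving decision table together with a
#' [ScreeningReport].
#'
#' @param decisions A decision table from [decide_trials()].
#' @param accuracy_threshold Participant accuracy gate (default 0.70).
#' @param max_trial_s Maximum trial duration (default 5.2 s).
#' @return A list: `data` (screened decision table, always-on-target trials
#'   retained as `NA` decision times), `report` (class
#'   `mf_screening_report`).
#' @export
screen_decisions <- function(decisions, accuracy_threshold = 0.70,
                             max_trial_s = 5.2) {
  acc <- tapply(decisions$caught, decisions$participant, mean)
  gate <- gate_participants(acc, accuracy_threshold)
  n0 <- nrow(decisions)
  d1 <- decisions[decisions$participant %in% gate$kept$participant, , drop = FALSE]
  verdict <- filter_trials(d1, max_trial_s)
  d2 <- d1[verdict == "keep", , drop = FALSE]
  lost_aot <- sum(d2$na_reason == "always_on_target")
  report <- structure(
    list(participants_dropped = gate$dropped,
         n_trials_start = n0,
         trials_dropped_early_click = sum(verdict == "early_click"),
         trials_dropped_slow = sum(verdict == "slow_trial"),
         trials_lost_always_on_target = lost_aot,
         frac_after_participant_gate = nrow(d1) / n0,
         frac_after_trial_filters = nrow(d2) / n0,
         frac_with_decision_time = sum(d2$na_reason == "none") / n0),
    class = "mf_screening_report")
  list(data = d2, report = report)
}

#' @export
print.mf_screening_report <- function(x, ...) {
  cat("<mf_screening_report>\n")
  cat(sprintf("  participants dropped (<70%% correct): %d\n",
              nrow(x$participants_dropped)))
  if (nrow(x$participants_dropped))
    cat(sprintf("    %s (%.0f%%)\n", x$participants_dropped$participant,
                100 * x$participants_dropped$accuracy), sep = "")
  cat(sprintf("  trials dropped: %d early clicks, %d slow (> 5.2 s)\n",
              x$trials_dropped_early_click, x$trials_dropped_slow))
  cat(sprintf("  trials lost, cursor always on target: %d\n",
              x$trials_lost_always_on_target))
  cat(sprintf("  data remaining after gates: %.1f%%; with decision time: %.1f%%\n",
              100 * x$frac_after_trial_filters, 100 * x$frac_with_decision_time))
  invisible(x)
}

#' Write a screening report as a machine-readable summary
#'
#' @param report An `mf_screening_report`.
#' @param path JSON file path.
#' @export
write_screening_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
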