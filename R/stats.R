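#' Within-participant (Morey) confidence-interval half-widths
#'
#' Repeated-measures error bars: values are first averaged to one cell mean
#' per participant and condition, then centered within participant
#' (subtracting the participant mean and adding the grand mean, removing
#' between-participant offsets), and the cell standard error of the
#' centered values is inflated by Morey's correction \eqn{\sqrt{J/(J-1)}}
#' for J conditions and multiplied by the t quantile with (number of
#' participants - 1) degrees of freedom.
#'
#' Participants with incomplete cells cannot be centered comparably and are
#' dropped from the CI computation (recorded in the `dropped` attribute).
#'
#' @param data A data frame.
#' @param value,participant,condition Column names (character scalars).
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row per condition: `condition`, `mean`,
#'   `n` (participants) and `ci_half_width`.
#' @export
morey_ci <- function(data, value = "decision_time_s",
                     participant = "participant", condition = "condition",
                     level = 0.95) {
  cells <- stats::aggregate(data[[value]],
                            list(participant = data[[participant]],
                                 condition = data[[condition]]),
                            mean)
  names(cells)[3] <- "value"
  J <- length(unique(cells$condition))
  if (J < 2) mf_stop("need at least 2 conditions for a within-participant CI",
                     "mf_parameter_error")
  counts <- table(cells$participant)
  complete <- names(counts)[counts == J]
  dropped <- setdiff(names(counts), complete)
  cells <- cells[cells$participant %in% complete, ]
  n <- length(complete)
  if (n < 2) mf_stop("need at least 2 participants with complete cells",
                     "mf_undefined_ci_error")
  pm <- tapply(cells$value, cells$participant, mean)
  grand <- mean(cells$value)
  cells$centered <- cells$value - pm[cells$participant] + grand
  out <- do.call(rbind, lapply(split(cells, cells$condition), function(cc) {
    se <- sd(cc$centered) / sqrt(n)
    data.frame(condition = cc$condition[1], mean = mean(cc$value), n = n,
               ci_half_width = se * sqrt(J / (J - 1)) *
                 qt(1 - (1 - level) / 2, df = n - 1))
  }))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Condition summary of decision times
#'
#' Cell means of decision time (in ms) by condition and response strategy
#' (clickers, who end trials with the tractor beam, vs non-clickers, who
#' wait for the objects to fall and contribute no reaction times), with
#' within-participant (Morey) CI half-widths per strategy group.
#'
#' @param decisions A (screened) decision table from [decide_trials()].
#' @param level Confidence level for the Morey CIs.
#' @return A data frame: `strategy`, `design`, `condition`, `mean_ms`,
#'   `n_participants`, `ci_half_width_ms`.
#' @export
condition_summary <- function(decisions, level = 0.95) {
  d <- decisions[!is.na(decisions$decision_time_s), , drop = FALSE]
  clicks <- tapply(!is.na(decisions$click_time_s), decisions$participant, any)
  d$strategy <- ifelse(clicks[d$participant], "clicker", "non_clicker")
  designs <- list(critical = "reduced", filler_semantic = "competitor")
  out <- list()
  for (strat in unique(d$strategy)) {
    for (cls in names(designs)) {
      fac <- designs[[cls]]
      sub <- d[d$strategy == strat & d$trial_class == cls & !is.na(d[[fac]]), ]
      if (length(unique(sub$participant)) < 2) next
      ci <- morey_ci(sub, value = "decision_time_s", condition = fac,
                     level = level)
      out[[length(out) + 1L]] <- data.frame(
        strategy = strat, design = cls, condition = ci$condition,
        mean_ms = 1000 * ci$mean, n_participants = ci$n,
        ci_half_width_ms = 1000 * ci$ci_half_width)
    }
  }
  do.call(rbind, out)
}

# internal: build an lmer formula from slope sets
build_formula <- function(dv, fixed, part_slopes, item_slopes, correlated) {
  bar <- function(slopes, grp) {
    inner <- if (length(slopes)) paste(c("1", slopes), collapse = " + ") else "1"
    op <- if (correlated || !length(slopes)) "|" else "||"
    sprintf("(%s %s %s)", inner, op, grp)
  }
  stats::as.formula(paste(dv, "~", fixed, "+", bar(part_slopes, "participant"),
                          "+", bar(item_slopes, "item_id")))
}

# internal: fit and classify convergence. Singular fits, optimizer
# failures and convergence warnings all send the ladder to the next
# simpler structure. The ladder itself uses plain lme4 fits without the
# costly post-hoc derivative check; the winning structure is refitted once
# with lmerTest for the Satterthwaite tests.
fit_step <- function(formula, data) {
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE,
                        control = lme4::lmerControl(
                          calc.derivs = FALSE,
                          check.conv.singular = "ignore")),
             error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error"))
    return(list(fit = NULL, ok = FALSE, why = conditionMessage(fit)))
  opt_bad <- !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0
  opt_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  bad <- length(warns) > 0 || opt_bad || length(opt_msgs) > 0 || singular
  why <- if (singular) "singular fit"
  else if (length(warns) || length(opt_msgs))
    paste(c(warns, opt_msgs), collapse = "; ")
  else if (opt_bad) "optimizer did not converge"
  else "converged"
  list(fit = fit, ok = !bad, why = why)
}

#' Fit the decision-time mixed model with a convergence ladder
#'
#' Decision times (ms) are modelled with linear mixed-effects models with
#' crossed random effects for participants and items. Modelling starts from
#' the full random-effect structure (random slopes for every within-unit
#' predictor: both contrast codes and their interaction over participants;
#' reduction over items, segment being a between-item property; for the
#' semantic design, predictability over both). When a fit does not converge
#' (including singular fits), the ladder first removes the correlations
#' between random effects, and then removes random slopes one at a time —
#' an interaction slope first, otherwise the slope with the smallest
#' estimated variance — until a fit converges. Fixed effects use the
#' \eqn{\pm 0.5} contrast codes, so facilitatory effects appear as negative
#' weights; t-tests use Satterthwaite degrees of freedom (reported in the
#' fit as `df_method`).
#'
#' @param decisions A screened decision table from [decide_trials()] /
#'   [screen_decisions()]; rows with `NA` decision times are dropped.
#' @param design `"reduction"` (critical trials: reduction x segment) or
#'   `"competitor"` (semantic fillers: predictability).
#' @return An `mf_model_fit`: `coefficients` (estimate, SE, df, t, p),
#'   `formula`, `trail` (structures attempted, with outcomes; non-empty
#'   beyond one entry iff the maximal structure was simplified), `fit` (the
#'   underlying `lmerModLmerTest`), `df_method`.
#' @export
fit_decision_model <- function(decisions, design = c("reduction", "competitor")) {
  design <- match.arg(design)
  if (design == "reduction") {
    d <- decisions[decisions$trial_class == "critical" &
                     !is.na(decisions$decision_time_s), ]
    fixed <- "reductionC * segmentC"
    part_slopes <- c("reductionC", "segmentC", "reductionC:segmentC")
    item_slopes <- "reductionC"
  } else {
    d <- decisions[decisions$trial_class == "filler_semantic" &
                     !is.na(decisions$decision_time_s), ]
    fixed <- "predictabilityC"
    part_slopes <- "predictabilityC"
    item_slopes <- "predictabilityC"
  }
  if (nrow(d) == 0L) mf_stop("no usable decision times for this design",
                             "mf_modelling_error")
  d$dt_ms <- 1000 * d$decision_time_s

  trail <- list()
  attempt <- function(correlated, ps, is) {
    f <- build_formula("dt_ms", fixed, ps, is, correlated)
    res <- fit_step(f, d)
    trail[[length(trail) + 1L]] <<- list(
      formula = deparse1(f), outcome = res$why)
    res
  }

  res <- attempt(TRUE, part_slopes, item_slopes)
  if (!res$ok) res <- attempt(FALSE, part_slopes, item_slopes)
  ps <- part_slopes; is_ <- item_slopes
  last <- res
  while (!last$ok && (length(ps) || length(is_))) {
    inter <- grep(":", ps, value = TRUE)
    if (length(inter)) {
      ps <- setdiff(ps, inter[1])
    } else {
      # remove the slope with the smallest estimated variance in the last
      # successful fit; without one, fall back to dropping the last slope
      cand <- c(if (length(ps)) paste0("participant.", ps),
                if (length(is_)) paste0("item_id.", is_))
      drop_name <- NULL
      if (!is.null(last$fit)) {
        vc <- as.data.frame(lme4::VarCorr(last$fit))
        vc <- vc[is.na(vc$var2) & vc$var1 %in% c(ps, is_), ]
        if (nrow(vc)) {
          sm <- vc[which.min(vc$vcov), ]
          drop_name <- paste0(sub("\\..*$", "", sm$grp), ".", sm$var1)
        }
      }
      if (is.null(drop_name))
        drop_name <- if (length(ps)) paste0("participant.", ps[length(ps)])
      else paste0("item_id.", is_[length(is_)])
      if (startsWith(drop_name, "participant."))
        ps <- setdiff(ps, sub("^participant\\.", "", drop_name))
      else is_ <- setdiff(is_, sub("^item_id\\.", "", drop_name))
    }
    last <- attempt(FALSE, ps, is_)
  }
  if (is.null(last$fit))
    mf_stop(paste("no decision-time model could be fitted; trail:",
                  paste(vapply(trail, `[[`, "", "outcome"), collapse = " -> ")),
            "mf_modelling_error")
  final <- suppressWarnings(suppressMessages(
    lmerTest::lmer(stats::as.formula(trail[[length(trail)]]$formula),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  co <- as.data.frame(summary(final)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  structure(
    list(coefficients = co, formula = trail[[length(trail)]]$formula,
         trail = trail, converged = last$ok, fit = final,
         df_method = "Satterthwaite", n_obs = nrow(d)),
    class = "mf_model_fit")
}

#' @export
print.mf_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mf_model_fit> %s\n  (t-tests with %s df; %d observations)\n",
              x$formula, x$df_method, x$n_obs))
  print(round(x$coefficients, digits))
  if (length(x$trail) > 1L)
    cat(sprintf("  random-effect structure simplified in %d step(s)\n",
                length(x$trail) - 1L))
  invisible(x)
}

#' Bootstrap time-course difference curve
#'
#' A distribution-free stand-in for a smooth-based time-course analysis:
#' per participant and condition the mean oriented trajectory is computed
#' on the 60 Hz grid; the condition difference is averaged over
#' participants, and a percentile cluster bootstrap (resampling
#' participants with replacement) gives a pointwise confidence band.
#' Maximal runs of grid points whose band excludes zero are reported as
#' significant time intervals. The intervals are not expected to coincide
#' with windows from a model-based smooth analysis of the same data.
#'
#' @param pre Result of [preprocess_logs()].
#' @param condition Name of the two-level metadata column to contrast.
#' @param levels Optional length-2 character: the difference is
#'   `levels[1] - levels[2]` (default: sorted unique values).
#' @param B Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param band `"simultaneous"` (default) scales the bootstrap standard
#'   error by the quantile of the maximum standardized deviation across
#'   grid points, controlling the family-wise error of the significance
#'   calls over the whole window; `"pointwise"` gives per-point percentile
#'   intervals (narrower, but with no multiplicity control — expect
#'   spurious short intervals under the null).
#' @param seed Integer seed for the bootstrap.
#' @return An `mf_timecourse`: `times`, `difference`, `lower`, `upper`,
#'   `intervals` (data frame of start/end seconds), `n_participants`.
#' @export
timecourse_difference <- function(pre, condition, levels = NULL, B = 2000,
                                  level = 0.95,
                                  band = c("simultaneous", "pointwise"),
                                  seed = NULL) {
  band <- match.arg(band)
  meta <- pre$meta
  keep <- !is.na(meta[[condition]])
  X <- pre$x[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (is.null(levels)) levels <- sort(unique(meta[[condition]]))
  stopifnot(length(levels) == 2L)
  curves <- function(lv) {
    idx <- meta[[condition]] == lv
    rowsum(X[idx, , drop = FALSE], meta$participant[idx]) /
      as.vector(table(meta$participant[idx])[sort(unique(meta$participant[idx]))])
  }
  c1 <- curves(levels[1]); c2 <- curves(levels[2])
  common <- intersect(rownames(c1), rownames(c2))
  if (length(common) < 2)
    mf_stop("need at least 2 participants with data in both conditions",
            "mf_analysis_error")
  D <- c1[common, , drop = FALSE] - c2[common, , drop = FALSE]
  diff_curve <- colMeans(D)
  P <- nrow(D)
  idx <- with_seed(seed, matrix(sample.int(P, P * B, replace = TRUE), nrow = B))
  if (band == "pointwise") {
    boot <- t(apply(idx, 1, function(ii) colMeans(D[ii, , drop = FALSE])))
    alpha <- (1 - level) / 2
    lower <- apply(boot, 2, quantile, probs = alpha, names = FALSE)
    upper <- apply(boot, 2, quantile, probs = 1 - alpha, names = FALSE)
  } else {
    # studentized max-statistic bootstrap: the standard error is
    # re-estimated inside each resample, so the quantile of the maximal
    # standardized deviation reflects both the curve's correlation
    # structure and the noise in the per-point SEs
    se <- apply(D, 2, sd) / sqrt(P)
    Tmax <- vapply(seq_len(B), function(b) {
      Db <- D[idx[b, ], , drop = FALSE]
      mb <- colMeans(Db)
      vb <- (colMeans(Db * Db) - mb^2) * P / (P - 1)
      seb <- sqrt(pmax(vb, 0)) / sqrt(P)
      ok <- seb > 0
      if (!any(ok)) return(0)
      max(abs(mb[ok] - diff_curve[ok]) / seb[ok])
    }, numeric(1))
    # small-sample floor: never narrower than the exact pointwise
    # Student-t interval on P participant differences
    q <- max(quantile(Tmax, probs = level, names = FALSE),
             qt(1 - (1 - level) / 2, df = P - 1))
    lower <- diff_curve - q * se
    upper <- diff_curve + q * se
  }
  sig <- lower > 0 | upper < 0
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  times <- pre$grid$times
  intervals <- data.frame(start_s = times[starts[runs$values]],
                          end_s = times[ends[runs$values]])
  structure(list(times = times, difference = diff_curve, lower = lower,
                 upper = upper, intervals = intervals,
                 n_participants = P, levels = levels, B = B, band = band),
            class = "mf_timecourse")
}

#' @export
print.mf_timecourse <- function(x, ...) {
  cat(sprintf("<mf_timecourse> %s - %s over %d participants (B = %d)\n",
              x$levels[1], x$levels[2], x$n_participants, x$B))
  if (nrow(x$intervals))
    cat(sprintf("  band excludes 0 in [%.3f, %.3f] s\n",
                x$intervals$start_s, x$intervals$end_s), sep = "")
  else cat("  no interval where the band excludes 0\n")
  invisible(x)
}

#' Plot mean oriented trajectories by condition
#'
#' @param pre Result of [preprocess_logs()].
#' @param condition Metadata column to split curves by.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(pre, condition) {
  meta <- pre$meta
  keep <- !is.na(meta[[condition]])
  df <- data.frame(
    time = rep(pre$grid$times, each = sum(keep)),
    x = as.vector(pre$x[keep, , drop = FALSE]),
    condition = rep(meta[[condition]][keep], times = pre$grid$n_points))
  agg <- stats::aggregate(x ~ time + condition, df, mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = time, y = x, colour = condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from target onset (s)",
                  y = "oriented cursor position (screen widths)") +
    ggplot2::theme_minimal()
}

#' Plot condition means of decision times with Morey error bars
#'
#' @param summary_df Result of [condition_summary()].
#' @return A ggplot object.
#' @export
plot_decision_summary <- function(summary_df) {
  ggplot2::ggplot(summary_df,
                  ggplot2::aes(x = condition, y = mean_ms, fill = strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_ms - ci_half_width_ms,
                   ymax = mean_ms + ci_half_width_ms),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::facet_wrap(~design, scales = "free_x") +
    ggplot2::labs(y = "decision time (ms)", x = NULL) +
    ggplot2::theme_minimal()
}
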