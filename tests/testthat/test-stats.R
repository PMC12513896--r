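test_that("Morey CIs remove participant offsets and match a hand calculation", {
  # pure participant offsets: centering makes the half-width zero
  d <- data.frame(participant = rep(c("a", "b", "c"), each = 2),
                  condition = rep(c("x", "y"), 3),
                  decision_time_s = c(1.0, 1.2, 2.0, 2.2, 3.0, 3.2))
  ci <- morey_ci(d, condition = "condition")
  expect_equal(ci$ci_half_width, c(0, 0), tolerance = 1e-12)
  expect_equal(ci$mean, c(2.0, 2.2))

  # hand-computable 3 x 2 table, J = 2 -> sqrt(2) correction
  vals <- c(1.0, 1.3, 1.4, 1.9, 0.8, 1.0)
  d2 <- data.frame(participant = rep(c("a", "b", "c"), each = 2),
                   condition = rep(c("x", "y"), 3),
                   decision_time_s = vals)
  pm <- tapply(vals, d2$participant, mean)
  grand <- mean(vals)
  centered <- vals - pm[d2$participant] + grand
  hand <- sapply(split(centered, d2$condition), function(v)
    sd(v) / sqrt(3) * sqrt(2) * qt(0.975, 2))
  ci2 <- morey_ci(d2, condition = "condition")
  expect_equal(ci2$ci_half_width, unname(hand))

  # scale equivariance
  d3 <- d2
  d3$decision_time_s <- 2 * d3$decision_time_s
  expect_equal(morey_ci(d3, condition = "condition")$ci_half_width,
               2 * ci2$ci_half_width)

  # with zero participant offsets the Morey half-width equals the classical
  # between-participant one times sqrt(J/(J-1)) exactly
  d4 <- data.frame(participant = rep(c("a", "b", "c", "d"), each = 2),
                   condition = rep(c("x", "y"), 4),
                   decision_time_s = c(1.0, 2.0, 0.9, 2.1, 1.1, 1.9, 1.05, 1.95))
  pm4 <- tapply(d4$decision_time_s, d4$participant, mean)
  expect_equal(unname(diff(range(pm4))), 0) # zero participant offsets by construction
  classical <- sapply(split(d4$decision_time_s, d4$condition), function(v)
    sd(v) / sqrt(4) * qt(0.975, 3))
  expect_equal(morey_ci(d4, condition = "condition")$ci_half_width,
               unname(classical) * sqrt(2))

  expect_error(morey_ci(d[d$participant == "a", ], condition = "condition"),
               class = "mf_undefined_ci_error")
})

# balanced synthetic decision table with known cell structure
balanced_table <- function(n_p = 12, n_i = 16, b_red = -0.07, noise = 0.04,
                           seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant = sprintf("p%02d", 1:n_p),
                   item_id = sprintf("i%02d", 1:n_i),
                   stringsAsFactors = FALSE)
  g$trial_class <- "critical"
  g$reduced <- ifelse((match(g$participant, unique(g$participant)) +
                         match(g$item_id, unique(g$item_id))) %% 2 == 0,
                      "present", "deleted")
  g$segment <- ifelse(match(g$item_id, unique(g$item_id)) %% 2 == 0,
                      "h", "glottal")
  g$reductionC <- contrast_code(g$reduced, "reduced")
  g$segmentC <- contrast_code(g$segment, "segment")
  p_off <- rnorm(n_p, 0, 0.05)[match(g$participant, unique(g$participant))]
  i_off <- rnorm(n_i, 0, 0.03)[match(g$item_id, unique(g$item_id))]
  g$decision_time_s <- 0.55 + b_red * g$reductionC + p_off + i_off +
    rnorm(nrow(g), 0, noise)
  g
}

test_that("the mixed-model ladder recovers an injected reduction cost", {
  tab <- balanced_table(b_red = -0.07, seed = 2)
  m <- fit_decision_model(tab, "reduction")
  co <- m$coefficients["reductionC", ]
  expect_lt(co$estimate, 0)
  expect_lt(abs(co$estimate - (-70)), 2 * co$se)
  expect_equal(m$df_method, "Satterthwaite")
  expect_gt(length(m$trail), 0)
  # simplification trail is non-trivial iff the structure was reduced
  if (length(m$trail) > 1) expect_false(m$trail[[1]]$outcome == "converged")
})

test_that("a balanced design puts the intercept at the grand mean of cell means", {
  tab <- balanced_table(noise = 0.02, seed = 3)
  m <- fit_decision_model(tab, "reduction")
  cells <- aggregate(decision_time_s ~ reduced + segment, tab, mean)
  expect_equal(m$coefficients["(Intercept)", "estimate"],
               1000 * mean(cells$decision_time_s), tolerance = 0.01)
})

test_that("condition-label permutation only flips the coefficient sign", {
  tab <- balanced_table(seed = 4)
  flipped <- tab
  flipped$reduced <- ifelse(tab$reduced == "present", "deleted", "present")
  flipped$reductionC <- contrast_code(flipped$reduced, "reduced")
  m1 <- fit_decision_model(tab, "reduction")
  m2 <- fit_decision_model(flipped, "reduction")
  expect_equal(m2$coefficients["reductionC", "estimate"],
               -m1$coefficients["reductionC", "estimate"], tolerance = 1e-4)
  expect_equal(m2$coefficients["(Intercept)", "estimate"],
               m1$coefficients["(Intercept)", "estimate"], tolerance = 1e-4)
})

# synthetic participant-mean trajectories around a known difference curve
timecourse_fixture <- function(n_p, sep_after_onset, noise_sd, seed) {
  set.seed(seed)
  g <- grid_spec()
  n <- g$n_points
  X <- matrix(NA_real_, 2 * n_p * 2, n)
  meta <- data.frame(participant = character(2 * n_p * 2),
                     competitor = character(2 * n_p * 2))
  base <- 0.4 / (1 + exp(-(g$times - 0.5) / 0.15))
  row <- 0
  for (p in seq_len(n_p)) for (cond in c("similar", "different"))
    for (rep_i in 1:2) {
      row <- row + 1
      shift <- if (cond == "different" ) sep_after_onset * (g$times > 0) else 0
      X[row, ] <- base + shift + rnorm(1, 0, 0.03) + rnorm(n, 0, noise_sd)
      meta$participant[row] <- sprintf("p%02d", p)
      meta$competitor[row] <- cond
    }
  list(x = X, meta = meta, grid = g)
}

test_that("the bootstrap difference curve flags an injected separation after onset", {
  fx <- timecourse_fixture(n_p = 24, sep_after_onset = 0.1, noise_sd = 0.02,
                           seed = 11)
  tc <- timecourse_difference(fx, "competitor",
                              levels = c("different", "similar"),
                              B = 500, seed = 12)
  expect_gt(nrow(tc$intervals), 0)
  expect_gt(tc$intervals$start_s[1], 0)    # separation only exists post-onset
  expect_gt(max(tc$difference), 0.05)
})

test_that("a condition differenced with itself is identically zero", {
  set.seed(13)
  g <- grid_spec()
  curves <- matrix(rnorm(6 * g$n_points, 0, 0.05), 6)
  fx <- list(x = rbind(curves, curves),
             meta = data.frame(participant = rep(sprintf("p%d", 1:6), 2),
                               competitor = rep(c("similar", "different"),
                                                each = 6)),
             grid = g)
  tc <- timecourse_difference(fx, "competitor", B = 200, seed = 14)
  expect_equal(max(abs(tc$difference)), 0)
  expect_equal(nrow(tc$intervals), 0)
})

test_that("the simultaneous band stays quiet under the null", {
  # nominal 5% family-wise rate: over 20 null runs, more than 3 flagged
  # runs would be inconsistent with calibration (binomial p < 0.02)
  clean <- 0
  for (s in 1:20) {
    fx <- timecourse_fixture(n_p = 20, sep_after_onset = 0, noise_sd = 0.02,
                             seed = 500 + s)
    tc <- timecourse_difference(fx, "competitor", B = 500, seed = 600 + s)
    if (nrow(tc$intervals) == 0) clean <- clean + 1
  }
  expect_gte(clean, 17)
})

test_that("bootstrap results are seed-reproducible", {
  fx <- timecourse_fixture(n_p = 8, sep_after_onset = 0.05, noise_sd = 0.02,
                           seed = 21)
  a <- timecourse_difference(fx, "competitor", B = 200, seed = 7)
  b <- timecourse_difference(fx, "competitor", B = 200, seed = 7)
  expect_identical(a$lower, b$lower)
  expect_identical(a$intervals, b$intervals)
})

test_that("condition summaries split clickers from non-clickers", {
  fx <- quick_cohort(8, seed = 71, effect_map = c(reduced = 0.06, similar = 0.135),
                     clicker_prob = 0.6)
  sc <- screen_decisions(fx)
  cs <- condition_summary(sc$data)
  expect_true(all(c("strategy", "condition", "mean_ms", "ci_half_width_ms")
                  %in% names(cs)))
  expect_true(all(cs$ci_half_width_ms >= 0))
  expect_true(any(cs$strategy == "clicker"))
  # decision times live in a plausible range (a few hundred ms)
  expect_true(all(cs$mean_ms > 0 & cs$mean_ms < 2000))
})
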