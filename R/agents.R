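#' Synthetic participant profile
#'
#' A synthetic participant is described by a latent commitment process: at
#' `base_commit_s` seconds after the target-word onset (shifted additively
#' by condition effects and Gaussian noise) the agent commits to one object
#' and starts tracking it; before that the cursor jitters around the screen
#' centre. Tracking is an exponential relaxation toward the chosen object's
#' current position with time constant `track_lag_s`. Clicker agents
#' activate the tractor beam `click_delay_s` after committing, as soon as
#' the cursor is within the catch tolerance of the chosen object;
#' non-clickers let the objects fall and therefore contribute no reaction
#' times. With probability `guess_prob` the agent guesses a side before the
#' target onset; correct guesses produce the always-on-target trials that
#' are lost to decision-time extraction.
#'
#' @param base_commit_s Mean commitment latency after target onset (s).
#' @param effect_map Named additive commitment shifts (s): `reduced` applies
#'   to critical trials with a deleted initial segment, `similar` to filler
#'   trials with a similar semantic competitor.
#' @param commit_sd_s SD of the zero-mean commitment noise (s).
#' @param track_lag_s Exponential-approach time constant of tracking (s).
#' @param jitter_sd SD of white positional cursor noise (screen widths).
#' @param is_clicker Whether the agent ends trials with the tractor beam.
#' @param click_delay_s Commitment-to-click latency (s).
#' @param guess_prob Probability of guessing a random side before onset.
#' @param host_fps Frame rate of the agent's (simulated) host computer.
#' @param t_jitter_ms Half-width of uniform timestamp jitter (ms) applied to
#'   logged frame times, emulating imprecise browser clocks.
#' @param id Participant id token.
#' @return An object of class `mf_agent`.
#' @export
agent_profile <- function(base_commit_s = 0.5,
                          effect_map = c(reduced = 0.060, similar = 0.135),
                          commit_sd_s = 0.15, track_lag_s = 0.15,
                          jitter_sd = 0.003, is_clicker = TRUE,
                          click_delay_s = 0.3, guess_prob = 0.04,
                          host_fps = 60, t_jitter_ms = 0,
                          id = NA_character_) {
  if (any(c(base_commit_s, commit_sd_s, track_lag_s, jitter_sd,
            click_delay_s, t_jitter_ms) < 0))
    mf_stop("agent latencies and noise SDs must be non-negative", "mf_parameter_error")
  if (guess_prob < 0 || guess_prob > 1)
    mf_stop("guess_prob must be in [0, 1]", "mf_parameter_error")
  if (!host_fps %in% c(30, 60, 75, 144))
    mf_stop("host_fps must be one of 30, 60, 75, 144", "mf_parameter_error")
  structure(
    list(base_commit_s = base_commit_s, effect_map = effect_map,
         commit_sd_s = commit_sd_s, track_lag_s = track_lag_s,
         jitter_sd = jitter_sd, is_clicker = isTRUE(is_clicker),
         click_delay_s = click_delay_s, guess_prob = guess_prob,
         host_fps = host_fps, t_jitter_ms = t_jitter_ms, id = id),
    class = "mf_agent"
  )
}

# internal: additive commitment shift for the trial's condition
commitment_shift <- function(agent, config) {
  shift <- 0
  em <- agent$effect_map
  if (config$trial_class == "critical" && identical(config$reduced, "deleted"))
    shift <- shift + unname(em["reduced"] %||% 0)
  if (config$trial_class == "filler_semantic" && identical(config$competitor, "similar"))
    shift <- shift + unname(em["similar"] %||% 0)
  shift
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Draw a commitment time and side choice for one trial
#'
#' With probability `guess_prob` the agent commits to a uniformly random
#' side before the target onset (a pre-onset guess); otherwise it commits to
#' the target side at `base_commit_s` plus the applicable condition shifts
#' plus zero-mean Gaussian noise (truncated at 0: the agent cannot use
#' target information before the onset).
#'
#' @param agent An [agent_profile()].
#' @param config An [trial_config()].
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A list with `commit_rel_s` (seconds relative to target onset),
#'   `side` (`"left"`/`"right"`) and `guessed`.
#' @export
draw_commitment <- function(agent, config, seed = NULL) {
  with_seed(seed, {
    onset <- config$target_onset_s
    if (runif(1) < agent$guess_prob) {
      # an initial guess: the agent picks a side shortly after the trial
      # starts (0.2-0.6 s into the routine), well before the target word on
      # most trials, so correct guesses are typically on the target for the
      # whole analysis window
      side <- sample(c("left", "right"), 1L)
      commit_abs <- min(runif(1, 0.2, 0.6), onset - 0.05)
      list(commit_rel_s = commit_abs - onset, side = side, guessed = TRUE)
    } else {
      commit <- agent$base_commit_s + commitment_shift(agent, config) +
        (if (agent$commit_sd_s > 0) rnorm(1, 0, agent$commit_sd_s) else 0)
      list(commit_rel_s = max(commit, 0), side = config$target_side,
           guessed = FALSE)
    }
  })
}

# internal: cursor x over the frame times. Before the absolute commitment
# time the cursor jitters around the centre; afterwards it relaxes toward
# the chosen object's path with per-frame gain alpha = 1 - exp(-dt/lag).
agent_cursor_path <- function(times, commit_abs, obj_x, alpha, jit) {
  n <- length(times)
  x <- numeric(n)
  pre <- times < commit_abs
  x[pre] <- jit[pre]
  start <- sum(pre) + 1L
  if (start <= n) {
    p <- 0  # tracking starts from the centre hold position
    for (i in start:n) {
      p <- p + alpha * (obj_x[i] - p)
      x[i] <- p + jit[i]
    }
  }
  x
}

#' Generate a population of synthetic participants
#'
#' Participant heterogeneity enters through the base commitment latency
#' (Gaussian across participants), the clicker/non-clicker strategy split
#' (default 80% clickers), and heterogeneous host frame rates drawn from
#' 30/60/75/144 fps with 1 ms timestamp jitter, emulating the variety of
#' host computers in a web-based sample.
#'
#' @param n Number of participants.
#' @param seed Integer seed; the population is a pure function of it.
#' @param clicker_prob Probability that a participant is a clicker.
#' @param base_mean_s,base_sd_s Mean and between-participant SD of
#'   `base_commit_s`.
#' @param effect_map Condition shifts passed to every agent (see
#'   [agent_profile()]).
#' @param fps_set Host frame rates sampled uniformly per participant.
#' @param ... Further arguments passed to [agent_profile()].
#' @return A list of [agent_profile()] objects with ids `"p01"`, `"p02"`, ...
#' @export
make_population <- function(n, seed = NULL, clicker_prob = 0.8,
                            base_mean_s = 0.5, base_sd_s = 0.12,
                            effect_map = c(reduced = 0.060, similar = 0.135),
                            fps_set = c(30, 60, 75, 144), ...) {
  with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n))
    bases <- pmax(rnorm(n, base_mean_s, base_sd_s), 0.05)
    clickers <- runif(n) < clicker_prob
    fps <- sample(fps_set, n, replace = TRUE)
    lapply(seq_len(n), function(i)
      agent_profile(base_commit_s = bases[i], effect_map = effect_map,
                    is_clicker = clickers[i], host_fps = fps[i],
                    t_jitter_ms = 1, id = ids[i], ...))
  })
}
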