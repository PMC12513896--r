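#' Adjust the fall duration to the target-word onset
#'
#' The falling speed is fixed per trial so that the objects reach their
#' lowest point at least `min_post_onset_s` seconds after the onset of the
#' target word in the audio; otherwise trials with late target onsets would
#' leave too little time to position the spaceship. The per-frame vertical
#' decrement is then `(top_y - bottom_y) / (result * fps)`.
#'
#' @param target_onset_s Onset of the target word (seconds into the audio).
#' @param base_fall_s Default fall duration (seconds).
#' @param min_post_onset_s Minimum post-onset time (seconds, default 2).
#' @return The fall duration in seconds: `max(base_fall_s, target_onset_s +
#'   min_post_onset_s)`.
#' @export
#' @examples
#' adjust_fall_duration(0.73, 3, 2) # 3: base duration already sufficient
#' adjust_fall_duration(3.26, 3, 2) # 5.26: extended for a late onset
adjust_fall_duration <- function(target_onset_s, base_fall_s, min_post_onset_s = 2.0) {
  if (any(c(target_onset_s, base_fall_s, min_post_onset_s) <= 0))
    mf_stop("all fall-duration arguments must be positive", "mf_parameter_error")
  pmax(base_fall_s, target_onset_s + min_post_onset_s)
}

#' State of one falling object
#'
#' @param x,y Normalized position.
#' @param dir Horizontal heading, -1 or +1.
#' @param speed_x,speed_y Per-frame step sizes (normalized units/frame).
#' @param corridor Closed x-interval the object is confined to.
#' @return An object of class `mf_object_state`.
#' @export
object_state <- function(x, y, dir, speed_x, speed_y, corridor) {
  stopifnot(dir %in% c(-1, 1), length(corridor) == 2L)
  corridor <- sort(corridor)
  if (x < corridor[1] || x > corridor[2])
    mf_stop("object x outside its corridor", "mf_parameter_error")
  structure(list(x = x, y = y, dir = dir, speed_x = speed_x,
                 speed_y = speed_y, corridor = corridor),
            class = "mf_object_state")
}

#' Advance a falling object by one frame
#'
#' The object reverses direction when the uniform draw `u` falls below
#' `flip_prob`, or — taking precedence — when the candidate step would leave
#' its corridor. Exactly one draw is consumed per object per frame
#' regardless of which rule fires. After the heading decision the object
#' advances horizontally by `dir * speed_x` (clamped to the corridor) and
#' falls by `speed_y`.
#'
#' @param state An [object_state()].
#' @param u Uniform draw in `[0, 1]` for this frame.
#' @param flip_prob Per-frame spontaneous direction-change probability.
#' @return The advanced `mf_object_state`.
#' @export
step_object <- function(state, u, flip_prob = 1 / 40) {
  candidate <- state$x + state$dir * state$speed_x
  boundary <- candidate < state$corridor[1] || candidate > state$corridor[2]
  if (boundary || u < flip_prob) state$dir <- -state$dir
  x <- state$x + state$dir * state$speed_x
  state$x <- min(max(x, state$corridor[1]), state$corridor[2])
  state$y <- state$y - state$speed_y
  state
}

# internal: full horizontal object path over n frames (frame 1 = start
# position, no step). u has length n - 1. Tight loop: called per trial.
object_path <- function(n, x0, dir0, corridor, sx, u, flip_prob) {
  x <- numeric(n)
  x[1] <- x0
  lo <- corridor[1]; hi <- corridor[2]
  d <- dir0
  xi <- x0
  if (n > 1L) for (i in 2:n) {
    cand <- xi + d * sx
    if (cand < lo || cand > hi || u[i - 1L] < flip_prob) d <- -d
    xi <- xi + d * sx
    if (xi < lo) xi <- lo else if (xi > hi) xi <- hi
    x[i] <- xi
  }
  x
}

#' Adjudicate a catch
#'
#' A trial counts as a successful catch when the horizontal distance between
#' the spaceship and the target object at the end of the animation is
#' strictly less than `catch_frac` of the screen width — independently of
#' whether the participant used the tractor-beam click or let the object
#' fall.
#'
#' @param ship_x,target_x Final normalized x positions.
#' @param catch_frac Tolerance as a fraction of screen width.
#' @return Logical flag.
#' @export
#' @examples
#' adjudicate_catch(0.10, 0.14, 0.05) # TRUE: |diff| = 0.04 < 0.05
#' adjudicate_catch(0.10, 0.15, 0.05) # FALSE: boundary is strict
adjudicate_catch <- function(ship_x, target_x, catch_frac = 0.05) {
  stopifnot(abs(ship_x) <= 0.5, abs(target_x) <= 0.5)
  abs(ship_x - target_x) < catch_frac
}

#' Simulate one trial of the falling-objects task
#'
#' Frame-based generative model of the animation routine. The audio starts
#' at routine time 0; two objects fall from `top_y` to `bottom_y` over the
#' onset-adjusted fall duration while wiggling horizontally inside their
#' corridors. The synthetic participant (see [agent_profile()]) keeps the
#' spaceship near the centre until its latent commitment time, then tracks
#' the chosen object; clicker agents activate the tractor beam once aligned
#' with it. Termination follows the task rules: a click after the end of the
#' audio ends the routine `tail_s` later; a click during the audio ends it
#' `tail_s` after the audio ends; without a click the routine ends when the
#' objects reach their lowest point. All animations freeze at the click.
#'
#' @param config An [trial_config()].
#' @param geometry An [screen_geometry()].
#' @param params An [kinematics_params()].
#' @param agent An [agent_profile()].
#' @param seed Integer seed fixing all randomness of the trial.
#' @param participant Optional participant id stored in the log.
#' @return An object of class `mf_trial_log`: the trial config, a
#'   `data.frame` of frames (`t`, `x`, `y`, `button`, `obj_left_x`,
#'   `obj_right_x`, `obj_y`), `click_time_s`, `end_time_s`, `end_reason`
#'   (`"click"`, `"audio_tail"` or `"objects_reached_bottom"`), and `caught`.
#' @export
simulate_trial <- function(config, geometry = screen_geometry(),
                           params = kinematics_params(), agent = agent_profile(),
                           seed = NULL, participant = NA_character_) {
  # simulate in a canonical target-on-right frame and mirror afterwards, so
  # that a trial and its mirrored twin are exact negations under one seed
  if (config$target_side == "left") {
    log <- sim_trial_impl(mirror_trial_config(config), geometry, params,
                          agent, seed, participant)
    return(mirror_trial_log(log))
  }
  sim_trial_impl(config, geometry, params, agent, seed, participant)
}

sim_trial_impl <- function(config, geometry, params, agent, seed, participant) {
  with_seed(seed, {
    fps <- agent$host_fps
    dt <- 1 / fps
    onset <- config$target_onset_s
    t_fall <- adjust_fall_duration(onset, params$base_fall_s, params$min_post_onset_s)
    n_max <- as.integer(ceiling((max(t_fall, config$audio_dur_s) + params$tail_s) * fps)) + 2L
    times <- (seq_len(n_max) - 1) * dt

    # --- objects (independent wiggle draws, one per object per frame) ---
    sx <- params$speed_x / fps
    sy <- (geometry$top_y - geometry$bottom_y) / (t_fall * fps)
    u_l <- runif(n_max - 1L); u_r <- runif(n_max - 1L)
    dir_l <- sample(c(-1, 1), 1L); dir_r <- sample(c(-1, 1), 1L)
    xl <- object_path(n_max, mean(geometry$corridor_left), dir_l,
                      geometry$corridor_left, sx, u_l, params$flip_prob)
    xr <- object_path(n_max, mean(geometry$corridor_right), dir_r,
                      geometry$corridor_right, sx, u_r, params$flip_prob)
    oy <- pmax(geometry$top_y - (geometry$top_y - geometry$bottom_y) *
                 pmin(times, t_fall) / t_fall, geometry$bottom_y)

    # --- agent commitment and cursor path ---
    cm <- draw_commitment(agent, config)
    commit_abs <- onset + cm$commit_rel_s
    obj_x <- if (cm$side == "left") xl else xr
    jit <- if (agent$jitter_sd > 0) rnorm(n_max, 0, agent$jitter_sd) else numeric(n_max)
    alpha <- if (agent$track_lag_s <= 0) 1 else 1 - exp(-dt / agent$track_lag_s)
    cursor <- agent_cursor_path(times, commit_abs, obj_x, alpha, jit)

    # --- click detection (tractor beam), only while the animation runs ---
    click_i <- NA_integer_
    if (agent$is_clicker && is.finite(commit_abs)) {
      # a guessing agent starts tracking before the target onset but waits
      # for the word before activating the tractor beam
      click_from <- if (cm$guessed) max(commit_abs, onset) else commit_abs
      eligible <- which(times >= click_from + agent$click_delay_s &
                          times < t_fall &
                          abs(cursor - obj_x) < geometry$catch_frac)
      if (length(eligible)) click_i <- eligible[1L]
    }

    if (is.na(click_i)) {
      end_time <- t_fall
      end_reason <- "objects_reached_bottom"
      click_time <- NA_real_
    } else {
      click_time <- times[click_i]
      if (click_time < config$audio_dur_s) {
        end_time <- config$audio_dur_s + params$tail_s
        end_reason <- "audio_tail"
      } else {
        end_time <- click_time + params$tail_s
        end_reason <- "click"
      }
      # all animations stop at the click: freeze objects, cursor keeps
      # relaxing toward the frozen object position
      if (click_i < n_max) {
        idx <- (click_i + 1L):n_max
        xl[idx] <- xl[click_i]; xr[idx] <- xr[click_i]; oy[idx] <- oy[click_i]
        p <- cursor[click_i] - jit[click_i]
        fx <- obj_x[click_i]
        for (i in idx) {
          p <- p + alpha * (fx - p)
          cursor[i] <- p + jit[i]
        }
      }
    }

    keep <- times <= end_time + 1e-9
    n <- sum(keep)
    if (any(!is.finite(cursor[keep])))
      mf_stop("agent emitted a non-finite cursor position", "mf_simulation_error")
    cursor <- pmin(pmax(cursor, -0.5), 0.5)

    t_out <- times[seq_len(n)]
    if (agent$t_jitter_ms > 0 && n > 1L) {
      j <- agent$t_jitter_ms / 1000
      t_out[-1L] <- t_out[-1L] + runif(n - 1L, -j, j)
      stopifnot(all(diff(t_out) > 0))
    }
    button <- rep("up", n)
    if (!is.na(click_i) && click_i <= n) button[click_i] <- "down"

    frames <- structure(
      list(t = t_out, x = cursor[seq_len(n)], y = rep(geometry$ship_y, n),
           button = button, obj_left_x = xl[seq_len(n)],
           obj_right_x = xr[seq_len(n)], obj_y = oy[seq_len(n)]),
      class = "data.frame", row.names = c(NA, -n))
    target_x_final <- if (config$target_side == "left") frames$obj_left_x[n] else frames$obj_right_x[n]
    caught <- adjudicate_catch(frames$x[n], target_x_final, geometry$catch_frac)

    structure(
      list(config = config, participant = participant, frames = frames,
           click_time_s = click_time, end_time_s = end_time,
           end_reason = end_reason, caught = caught,
           fall_duration_s = t_fall, host_fps = fps,
           commit_rel_s = cm$commit_rel_s, commit_side = cm$side,
           guessed = cm$guessed),
      class = "mf_trial_log"
    )
  })
}

#' @export
print.mf_trial_log <- function(x, ...) {
  cat(sprintf(
    "<mf_trial_log> item %s (%s, target %s): %d frames @ %g fps, end by %s at %.3f s, %s\n",
    x$config$item_id, x$config$trial_class, x$config$target_side,
    nrow(x$frames), x$host_fps, x$end_reason, x$end_time_s,
    if (x$caught) "caught" else "missed"))
  invisible(x)
}

#' Mirror a trial log left/right
#'
#' Negates every x coordinate, swaps the object columns and mirrors the
#' config. Mirroring twice is the identity.
#'
#' @param log An `mf_trial_log`.
#' @return The mirrored log.
#' @export
mirror_trial_log <- function(log) {
  f <- log$frames
  x <- -f$x
  left <- -f$obj_right_x
  right <- -f$obj_left_x
  f$x <- x; f$obj_left_x <- left; f$obj_right_x <- right
  log$frames <- f
  log$config <- mirror_trial_config(log$config)
  log$commit_side <- if (log$commit_side == "left") "right" else "left"
  log
}
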