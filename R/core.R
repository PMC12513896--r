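#' @import data.table
#' @importFrom stats rnorm runif sd qt quantile resid sigma coef median
#' @importFrom utils head tail packageVersion
NULL

# internal: stop with a classed condition so callers/tests can distinguish
# validation errors from analysis failures
mf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mf_error")))
}

#' Screen geometry of the falling-objects task
#'
#' All coordinates are resolution-independent: `x` runs over
#' \eqn{[-0.5, +0.5]} in screen-width units with 0 at the screen centre, and
#' `y` over \eqn{[0, 1]} from bottom to top. Each falling object is confined
#' to a horizontal corridor on its side of the screen; the two corridors are
#' mirror-symmetric about the centre. A trial counts as a successful catch
#' when the final horizontal distance between spaceship and target object is
#' strictly less than `catch_frac` of the screen width.
#'
#' Corridor intervals are closed on both ends: a cursor sample exactly on a
#' corridor boundary counts as inside the corridor.
#'
#' @param ship_y Vertical spaceship position (normalized units).
#' @param top_y Vertical start position of the falling objects.
#' @param bottom_y Lowest object position, just above the spaceship.
#' @param corridor_left,corridor_right Closed x-intervals (length-2 numeric)
#'   the left and right objects wiggle in; must mirror each other about 0.
#' @param catch_frac Catch tolerance as a fraction of screen width
#'   (default 0.05, i.e. 5% of the screen width).
#' @return An object of class `mf_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' geom$corridor_right
screen_geometry <- function(ship_y = 0.05, top_y = 0.95, bottom_y = 0.12,
                            corridor_left = c(-0.40, -0.08),
                            corridor_right = c(0.08, 0.40),
                            catch_frac = 0.05) {
  stopifnot(length(corridor_left) == 2L, length(corridor_right) == 2L)
  corridor_left <- sort(corridor_left)
  corridor_right <- sort(corridor_right)
  if (!(corridor_left[1] >= -0.5 && corridor_left[2] < 0))
    mf_stop("corridor_left must lie within [-0.5, 0)", "mf_parameter_error")
  if (!(corridor_right[1] > 0 && corridor_right[2] <= 0.5))
    mf_stop("corridor_right must lie within (0, 0.5]", "mf_parameter_error")
  if (!isTRUE(all.equal(corridor_right, -rev(corridor_left))))
    mf_stop("corridors must be mirror-symmetric about x = 0", "mf_parameter_error")
  if (!(bottom_y < top_y))
    mf_stop("bottom_y must be below top_y", "mf_parameter_error")
  if (!(catch_frac > 0 && catch_frac < 0.5))
    mf_stop("catch_frac must be in (0, 0.5)", "mf_parameter_error")
  structure(
    list(width = 1.0, ship_y = ship_y, top_y = top_y, bottom_y = bottom_y,
         corridor_left = corridor_left, corridor_right = corridor_right,
         catch_frac = catch_frac),
    class = "mf_geometry"
  )
}

#' Kinematic parameters of the animation routine
#'
#' The two objects fall at a constant vertical rate fixed per trial so that
#' they reach their lowest point no earlier than `min_post_onset_s` seconds
#' after the target-word onset (see [adjust_fall_duration()]). Horizontally
#' they move at `speed_x` screen widths per second and reverse direction
#' either when a per-frame uniform draw falls below `flip_prob` or when the
#' next step would leave their corridor.
#'
#' @param fps Nominal frame rate of the game loop (frames/second).
#' @param flip_prob Per-frame probability of a spontaneous direction change
#'   (default 1/40).
#' @param min_post_onset_s Minimum time between target-word onset and the
#'   objects reaching their lowest point (default 2 s).
#' @param base_fall_s Default fall duration used when the target onset is
#'   early enough not to force an extension (default 3 s).
#' @param tail_s Delay between the event ending a trial (click, or end of
#'   the audio for clicks during playback) and the end of the animation
#'   routine (default 0.2 s).
#' @param speed_x Horizontal object speed in screen widths per second.
#' @return An object of class `mf_kinematics`.
#' @export
kinematics_params <- function(fps = 60, flip_prob = 1 / 40,
                              min_post_onset_s = 2.0, base_fall_s = 3.0,
                              tail_s = 0.2, speed_x = 0.25) {
  if (!(flip_prob > 0 && flip_prob < 1))
    mf_stop("flip_prob must be in (0, 1)", "mf_parameter_error")
  if (!(min_post_onset_s > 0))
    mf_stop("min_post_onset_s must be positive", "mf_parameter_error")
  if (!(fps > 0 && base_fall_s > 0 && tail_s >= 0 && speed_x > 0))
    mf_stop("fps, base_fall_s and speed_x must be positive; tail_s non-negative",
            "mf_parameter_error")
  structure(
    list(fps = fps, flip_prob = flip_prob, min_post_onset_s = min_post_onset_s,
         base_fall_s = base_fall_s, tail_s = tail_s, speed_x = speed_x),
    class = "mf_kinematics"
  )
}

#' Configuration of a single trial
#'
#' Critical trials manipulate the reduction of the target word's initial
#' segment (`segment` /h/ vs glottal stop; `reduced` present vs deleted) and
#' carry no competitor manipulation; semantic filler trials manipulate
#' whether the second on-screen object is a semantic competitor or an
#' unrelated distractor and carry no segment/reduction codes.
#'
#' @param trial_index 1-based position of the trial in its session.
#' @param trial_class `"critical"` or `"filler_semantic"`.
#' @param target_side `"left"` or `"right"`.
#' @param target_onset_s Onset of the target word in the audio (seconds).
#' @param audio_dur_s Total duration of the audio (seconds).
#' @param item_id Item token.
#' @param is_practice Practice-block flag.
#' @param segment `"h"` or `"glottal"` (critical trials only).
#' @param reduced `"present"` or `"deleted"` (critical trials only).
#' @param competitor `"similar"` or `"different"` (filler trials only).
#' @return An object of class `mf_trial_config`.
#' @export
trial_config <- function(trial_index, trial_class, target_side,
                         target_onset_s, audio_dur_s, item_id,
                         is_practice = FALSE,
                         segment = NA_character_, reduced = NA_character_,
                         competitor = NA_character_) {
  trial_class <- match.arg(trial_class, c("critical", "filler_semantic"))
  target_side <- match.arg(target_side, c("left", "right"))
  if (!(target_onset_s > 0 && target_onset_s < audio_dur_s))
    mf_stop("need 0 < target_onset_s < audio_dur_s", "mf_parameter_error")
  if (trial_class == "critical") {
    if (is.na(segment) || is.na(reduced) || !is.na(competitor))
      mf_stop("critical trials carry segment + reduced and no competitor",
              "mf_parameter_error")
    segment <- match.arg(segment, c("h", "glottal"))
    reduced <- match.arg(reduced, c("present", "deleted"))
  } else {
    if (is.na(competitor) || !is.na(segment) || !is.na(reduced))
      mf_stop("filler trials carry competitor and no segment/reduced codes",
              "mf_parameter_error")
    competitor <- match.arg(competitor, c("similar", "different"))
  }
  structure(
    list(trial_index = as.integer(trial_index), is_practice = isTRUE(is_practice),
         trial_class = trial_class, target_side = target_side,
         segment = segment, reduced = reduced, competitor = competitor,
         target_onset_s = target_onset_s, audio_dur_s = audio_dur_s,
         item_id = as.character(item_id)),
    class = "mf_trial_config"
  )
}

#' Mirror a trial configuration left/right
#'
#' Swaps the target side. Mirroring twice is the identity. The corresponding
#' transformation of a trial log negates all x coordinates and swaps the two
#' object columns.
#'
#' @param config An `mf_trial_config`.
#' @return The mirrored `mf_trial_config`.
#' @export
mirror_trial_config <- function(config) {
  config$target_side <- if (config$target_side == "left") "right" else "left"
  config
}

# contrast schemes: the "more" level always maps on +0.5 (segment present;
# /h/, which is orthographically coded; target predictable, i.e. the other
# object is an unrelated distractor)
mf_contrast_schemes <- list(
  reduced    = c(present = +0.5, deleted = -0.5),
  segment    = c(h = +0.5, glottal = -0.5),
  competitor = c(different = +0.5, similar = -0.5)
)

#' Contrast-code a two-level factor level
#'
#' Implements the sum-to-zero \eqn{\pm 0.5} coding used throughout the
#' analysis: the level that is "more" is always mapped on the positive
#' number — initial segment present (+0.5) vs deleted (-0.5); /h/ (+0.5,
#' orthographically coded) vs glottal stop (-0.5); target semantically
#' predictable, i.e. the other object is an unrelated distractor (+0.5), vs
#' a similar competitor (-0.5). Because decision times are a latency,
#' facilitatory effects show up as negative regression weights under this
#' coding.
#'
#' @param level A factor level (character scalar or vector).
#' @param scheme Name of a built-in scheme (`"reduced"`, `"segment"`,
#'   `"competitor"`) or a named numeric mapping.
#' @return The signed half-unit code(s); `NA` input yields `NA`.
#' @export
#' @examples
#' contrast_code("present", "reduced")   # +0.5
#' contrast_code("glottal", "segment")   # -0.5
contrast_code <- function(level, scheme) {
  map <- if (is.character(scheme) && length(scheme) == 1L) {
    if (!scheme %in% names(mf_contrast_schemes))
      mf_stop(sprintf("unknown contrast scheme '%s'", scheme), "mf_coding_error")
    mf_contrast_schemes[[scheme]]
  } else {
    stopifnot(is.numeric(scheme), !is.null(names(scheme)))
    scheme
  }
  out <- rep(NA_real_, length(level))
  known <- is.na(level) | level %in% names(map)
  if (!all(known))
    mf_stop(sprintf("unknown level(s) for contrast coding: %s",
                    paste(unique(level[!known]), collapse = ", ")),
            "mf_coding_error")
  ok <- !is.na(level)
  out[ok] <- unname(map[level[ok]])
  out
}

#' Default flat configuration
#'
#' All tunable geometry, kinematics and threshold parameters as a flat,
#' typed key-value list, suitable for serialization with [write_config()].
#'
#' @return A named list of scalar parameters.
#' @export
mf_default_config <- function() {
  g <- screen_geometry()
  k <- kinematics_params()
  list(
    ship_y = g$ship_y, top_y = g$top_y, bottom_y = g$bottom_y,
    corridor_inner = g$corridor_right[1], corridor_outer = g$corridor_right[2],
    catch_frac = g$catch_frac,
    fps = k$fps, flip_prob = k$flip_prob,
    min_post_onset_s = k$min_post_onset_s, base_fall_s = k$base_fall_s,
    tail_s = k$tail_s, speed_x = k$speed_x,
    grid_t_start = -0.5, grid_t_end = 2.0, grid_rate = 60,
    eps = 1e-3,
    accuracy_threshold = 0.70, max_trial_s = 5.2,
    n_participants = 40, clicker_prob = 0.8, guess_prob = 0.04,
    base_commit_s = 0.5, base_commit_sd_s = 0.12, commit_sd_s = 0.15,
    track_lag_s = 0.15, jitter_sd = 0.003, click_delay_s = 0.3,
    effect_reduced_s = 0.060, effect_similar_s = 0.135
  )
}

#' Write / read a flat key-value configuration file
#'
#' @param config Named list of scalar values (see [mf_default_config()]).
#' @param path File path (YAML, flat mapping).
#' @return `read_config()` returns the named list with defaults filled in
#'   for missing keys.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    mf_stop(sprintf("config file not found: %s", path), "mf_validation_error")
  cfg <- yaml::read_yaml(path)
  defaults <- mf_default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    mf_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            "mf_validation_error")
  out <- utils::modifyList(defaults, cfg)
  bad <- names(out)[!vapply(out, function(v) is.numeric(v) && length(v) == 1L, TRUE)]
  if (length(bad))
    mf_stop(sprintf("config key(s) not scalar numeric: %s",
                    paste(bad, collapse = ", ")), "mf_validation_error")
  out
}

# internal: build geometry/kinematics objects from a flat config list
config_geometry <- function(cfg) {
  screen_geometry(ship_y = cfg$ship_y, top_y = cfg$top_y, bottom_y = cfg$bottom_y,
                  corridor_left = c(-cfg$corridor_outer, -cfg$corridor_inner),
                  corridor_right = c(cfg$corridor_inner, cfg$corridor_outer),
                  catch_frac = cfg$catch_frac)
}

config_kinematics <- function(cfg) {
  kinematics_params(fps = cfg$fps, flip_prob = cfg$flip_prob,
                    min_post_onset_s = cfg$min_post_onset_s,
                    base_fall_s = cfg$base_fall_s, tail_s = cfg$tail_s,
                    speed_x = cfg$speed_x)
}

# internal: run expr with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# internal: derive a reproducible child seed below 2^31
child_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (k in ids) x <- (x * 48271 + as.double(k)) %% 2147483647
  as.integer(x)
}
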