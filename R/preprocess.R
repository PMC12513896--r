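#' Fixed analysis time grid
#'
#' The analysis grid runs from 0.5 s before the target-word onset to 2 s
#' after it at 60 Hz (one point every 16.67 ms), giving 151 points. Grid
#' timestamps are computed as `t_start + i/rate` (i = 0..n-1) so the point
#' count is exact on every platform.
#'
#' @param t_start,t_end Window relative to target onset (s).
#' @param rate Grid rate (Hz).
#' @return An object of class `mf_grid` with elements `t_start`, `t_end`,
#'   `rate`, `n_points` and `times`.
#' @export
grid_spec <- function(t_start = -0.5, t_end = 2.0, rate = 60) {
  n_points <- as.integer(round((t_end - t_start) * rate) + 1)
  structure(list(t_start = t_start, t_end = t_end, rate = rate,
                 n_points = n_points,
                 times = t_start + (seq_len(n_points) - 1) / rate),
            class = "mf_grid")
}

# internal: nearest-in-time lookup of observed x at the grid times.
# t_rel are the observed times relative to target onset (strictly
# increasing); ties (a grid point exactly halfway) resolve to the earlier
# sample; grid points beyond the observations take the first/last sample.
regrid_x <- function(t_rel, x, grid) {
  n <- length(t_rel)
  g <- grid$times
  idx <- findInterval(g, t_rel)          # last observation at or before g
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, n)
  d_lo <- g - t_rel[lo]
  d_hi <- t_rel[hi] - g
  pick <- ifelse(idx < 1L, hi, ifelse(idx >= n, lo,
                                      ifelse(d_lo <= d_hi, lo, hi)))
  x[pick]
}

#' Regrid a variable-frame-rate cursor log onto the analysis grid
#'
#' Web-collected cursor positions arrive at the host's frame times, which
#' differ across participants and trials. For each point of the fixed 60 Hz
#' grid the temporally nearest observed cursor position is used (a grid
#' point exactly halfway between two samples takes the earlier one). Grid
#' points after the last observation — e.g. after an early click ended the
#' trial — are padded with the last observed position (`pad_from` records
#' the first padded grid index, 1-based); points before the first
#' observation take the first position, the natural extension since
#' participants start on the spaceship at the screen centre.
#'
#' @param frames A data frame of frame samples with columns `t` (seconds
#'   since routine start, strictly increasing) and `x`.
#' @param target_onset_s Target-word onset (s since routine start).
#' @param grid A [grid_spec()].
#' @return An object of class `mf_trajectory` (unoriented): `x` of length
#'   `grid$n_points`, `grid`, `pad_from` (NA if no padding), `oriented =
#'   FALSE`.
#' @export
regrid <- function(frames, target_onset_s, grid = grid_spec()) {
  if (is.null(frames) || nrow(frames) == 0L)
    mf_stop("cannot regrid an empty frame list", "mf_preprocessing_error")
  t_rel <- frames$t - target_onset_s
  if (is.unsorted(t_rel, strictly = TRUE))
    mf_stop("frame timestamps must be strictly increasing", "mf_preprocessing_error")
  x <- regrid_x(t_rel, frames$x, grid)
  after <- which(grid$times > t_rel[length(t_rel)])
  structure(list(x = x, grid = grid,
                 pad_from = if (length(after)) after[1L] else NA_integer_,
                 oriented = FALSE, target_side = NA_character_),
            class = "mf_trajectory")
}

#' Orient a trajectory toward the target
#'
#' Multiplies the x coordinates by -1 if the target was on the left side,
#' so that positive positions always mean "closer to the target".
#' Applying the operation twice restores the original trajectory.
#'
#' @param traj An `mf_trajectory`.
#' @param target_side `"left"` or `"right"`.
#' @return The oriented `mf_trajectory`.
#' @export
orient <- function(traj, target_side) {
  target_side <- match.arg(target_side, c("left", "right"))
  if (target_side == "left") traj$x <- -traj$x
  traj$oriented <- !isTRUE(traj$oriented)
  traj$target_side <- target_side
  traj
}

#' Preprocess trial logs into oriented grid trajectories
#'
#' Bulk path from raw logs to the analysis representation: each log is
#' regridded onto the 60 Hz grid and oriented toward its target. Practice
#' trials are dropped.
#'
#' @param logs A list of `mf_trial_log` (optionally nested by participant).
#' @param grid A [grid_spec()].
#' @return A list with `x`: a numeric matrix (trials in rows, one column
#'   per grid point) of oriented positions, and `meta`: a `data.frame` of
#'   per-trial metadata (participant, item, condition codes and contrast
#'   codes, timing, end reason, catch flag, `pad_from`).
#' @export
preprocess_logs <- function(logs, grid = grid_spec()) {
  if (length(logs) && inherits(logs[[1]], "mf_trial_log")) logs <- list(logs)
  flat <- unlist(logs, recursive = FALSE)
  flat <- Filter(function(l) !l$config$is_practice, flat)
  if (!length(flat)) mf_stop("no experimental trials to preprocess", "mf_preprocessing_error")
  n <- length(flat)
  X <- matrix(NA_real_, n, grid$n_points)
  pad_from <- integer(n)
  for (i in seq_len(n)) {
    log <- flat[[i]]
    cfg <- log$config
    tr <- regrid(log$frames, cfg$target_onset_s, grid)
    X[i, ] <- if (cfg$target_side == "left") -tr$x else tr$x
    pad_from[i] <- tr$pad_from
  }
  cfg_field <- function(f, proto) vapply(flat, function(l) l$config[[f]], proto)
  log_field <- function(f, proto) vapply(flat, function(l) l[[f]], proto)
  meta <- data.frame(
    participant = log_field("participant", ""),
    item_id = cfg_field("item_id", ""),
    trial_index = cfg_field("trial_index", 0L),
    trial_class = cfg_field("trial_class", ""),
    target_side = cfg_field("target_side", ""),
    segment = cfg_field("segment", ""),
    reduced = cfg_field("reduced", ""),
    competitor = cfg_field("competitor", ""),
    target_onset_s = cfg_field("target_onset_s", 0),
    audio_dur_s = cfg_field("audio_dur_s", 0),
    click_time_s = log_field("click_time_s", 0),
    end_time_s = log_field("end_time_s", 0),
    end_reason = log_field("end_reason", ""),
    caught = log_field("caught", TRUE),
    pad_from = pad_from, stringsAsFactors = FALSE)
  meta$reductionC <- contrast_code(meta$reduced, "reduced")
  meta$segmentC <- contrast_code(meta$segment, "segment")
  meta$predictabilityC <- contrast_code(meta$competitor, "competitor")
  list(x = X, meta = meta, grid = grid)
}

#' Write / read preprocessed trajectories as wide delimited text
#'
#' One row per trial: metadata columns followed by the 151 oriented grid
#' positions (`x_001` ... `x_151`).
#'
#' @param pre The result of [preprocess_logs()].
#' @param path CSV file path.
#' @return `read_trajectories()` returns a list like [preprocess_logs()].
#' @export
write_trajectories <- function(pre, path) {
  X <- pre$x
  colnames(X) <- sprintf("x_%03d", seq_len(ncol(X)))
  data.table::fwrite(cbind(pre$meta, as.data.frame(X)), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path))
    mf_stop(sprintf("trajectory file not found: %s", path), "mf_io_error")
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  xcols <- grep("^x_\\d+$", names(dt), value = TRUE)
  if (!length(xcols))
    mf_stop("no trajectory columns (x_###) found", "mf_schema_error")
  X <- as.matrix(dt[, xcols, with = FALSE])
  dimnames(X) <- NULL
  meta <- as.data.frame(dt[, setdiff(names(dt), xcols), with = FALSE])
  list(x = X, meta = meta, grid = grid_spec(rate = (length(xcols) - 1) / 2.5))
}
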