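#' Default item inventory
#'
#' The experimental design uses 71 critical items (34 /h/-initial and 37
#' glottal-stop/vowel-initial words) and 25 semantic filler items, for 96
#' experimental trials per session, plus 5 practice items. Target-word
#' onsets are item properties drawn uniformly over the stimulus range
#' 0.73–3.26 s into the audio; audio continues for 0.9–1.9 s past the
#' onset.
#'
#' @param n_h,n_glottal,n_filler,n_practice Item counts per class.
#' @param seed Integer seed; the inventory is a pure function of it.
#' @param onset_range Range of target-word onsets (s into the audio).
#' @return A `data.frame` with columns `item_id`, `trial_class`, `segment`,
#'   `target_onset_s`, `audio_dur_s`, `is_practice`.
#' @export
item_inventory <- function(n_h = 34, n_glottal = 37, n_filler = 25,
                           n_practice = 5, seed = NULL,
                           onset_range = c(0.73, 3.26)) {
  with_seed(seed, {
    n <- n_h + n_glottal + n_filler + n_practice
    onset <- runif(n, onset_range[1], onset_range[2])
    dur <- onset + runif(n, 0.9, 1.9)
    data.frame(
      item_id = c(sprintf("h%02d", seq_len(n_h)),
                  sprintf("g%02d", seq_len(n_glottal)),
                  sprintf("f%02d", seq_len(n_filler)),
                  sprintf("x%02d", seq_len(n_practice))),
      trial_class = rep(c("critical", "critical", "filler_semantic",
                          "filler_semantic"),
                        c(n_h, n_glottal, n_filler, n_practice)),
      segment = rep(c("h", "glottal", NA, NA), c(n_h, n_glottal, n_filler, n_practice)),
      target_onset_s = onset, audio_dur_s = dur,
      is_practice = rep(c(FALSE, FALSE, FALSE, TRUE),
                        c(n_h, n_glottal, n_filler, n_practice)),
      stringsAsFactors = FALSE
    )
  })
}

#' Pre-compile counterbalanced session plans
#'
#' Builds `n_orders` session plans from an item inventory. Each plan holds
#' the 5-trial practice block, a seeded permutation of the 96 experimental
#' trials (every critical item exactly once), and performance-overview
#' pauses at trials 30, 60 and 90. Condition assignment is counterbalanced
#' within item across plans in a Latin-square-like alternation: each
#' critical item is reduced in exactly half of the plans, and each filler
#' item carries the similar competitor in exactly half, so that reduction
#' and competitor similarity are within-item predictors over participants.
#'
#' @param inventory An [item_inventory()] data frame.
#' @param n_orders Number of plans to pre-compile (default 32); must be even
#'   for exact counterbalancing.
#' @param seed Integer seed; order generation is a pure function of
#'   `(inventory, seed)`.
#' @return A list of `mf_session_plan` objects: `order_id`, `practice` and
#'   `trials` data frames (one row per [trial_config()]), `feedback_at`.
#' @export
generate_orders <- function(inventory, n_orders = 32, seed = NULL) {
  crit <- inventory[inventory$trial_class == "critical" & !inventory$is_practice, ]
  fill <- inventory[inventory$trial_class == "filler_semantic" & !inventory$is_practice, ]
  prac <- inventory[inventory$is_practice, ]
  deficits <- character(0)
  if (sum(crit$segment == "h") < 1 || sum(crit$segment == "glottal") < 1)
    deficits <- c(deficits, "need critical items of both segment classes")
  if (nrow(fill) < 1) deficits <- c(deficits, "need at least one filler item")
  if (nrow(prac) < 5)
    deficits <- c(deficits, sprintf("need 5 practice items, have %d", nrow(prac)))
  if (length(deficits))
    mf_stop(paste("inventory too small for the design:",
                  paste(deficits, collapse = "; ")), "mf_assembly_error")
  if (n_orders %% 2 != 0)
    mf_stop("n_orders must be even for exact counterbalancing", "mf_assembly_error")

  with_seed(seed, {
    n_trials <- nrow(crit) + nrow(fill)
    lapply(seq_len(n_orders), function(j) {
      # within-item alternation: item k gets condition A in plans of one
      # parity and condition B in the other -> exactly n_orders/2 each
      crit_red <- ifelse((seq_len(nrow(crit)) + j) %% 2 == 0, "deleted", "present")
      fill_cmp <- ifelse((seq_len(nrow(fill)) + j) %% 2 == 0, "similar", "different")
      exp_items <- rbind(
        data.frame(item_id = crit$item_id, trial_class = "critical",
                   segment = crit$segment, reduced = crit_red,
                   competitor = NA_character_,
                   target_onset_s = crit$target_onset_s,
                   audio_dur_s = crit$audio_dur_s, stringsAsFactors = FALSE),
        data.frame(item_id = fill$item_id, trial_class = "filler_semantic",
                   segment = NA_character_, reduced = NA_character_,
                   competitor = fill_cmp,
                   target_onset_s = fill$target_onset_s,
                   audio_dur_s = fill$audio_dur_s, stringsAsFactors = FALSE)
      )
      perm <- sample.int(n_trials)
      exp_items <- exp_items[perm, ]
      exp_items$target_side <- sample(rep(c("left", "right"),
                                          length.out = n_trials))
      exp_items$trial_index <- seq_len(n_trials)
      exp_items$is_practice <- FALSE
      practice <- data.frame(
        item_id = prac$item_id[1:5], trial_class = "filler_semantic",
        segment = NA_character_, reduced = NA_character_,
        competitor = sample(c("similar", "different"), 5, replace = TRUE),
        target_onset_s = prac$target_onset_s[1:5],
        audio_dur_s = prac$audio_dur_s[1:5],
        target_side = sample(rep(c("left", "right"), length.out = 5)),
        trial_index = seq_len(5), is_practice = TRUE,
        stringsAsFactors = FALSE
      )
      rownames(exp_items) <- NULL
      structure(list(order_id = j, practice = practice,
                     trials = exp_items,
                     feedback_at = seq(30, n_trials, by = 30)),
                class = "mf_session_plan")
    })
  })
}

#' @export
print.mf_session_plan <- function(x, ...) {
  cat(sprintf("<mf_session_plan> order %d: %d practice + %d experimental trials, pauses at %s\n",
              x$order_id, nrow(x$practice), nrow(x$trials),
              paste(x$feedback_at, collapse = "/")))
  invisible(x)
}

# internal: one plan row -> mf_trial_config
row_config <- function(row) {
  trial_config(trial_index = row$trial_index, trial_class = row$trial_class,
               target_side = row$target_side,
               target_onset_s = row$target_onset_s,
               audio_dur_s = row$audio_dur_s, item_id = row$item_id,
               is_practice = row$is_practice, segment = row$segment,
               reduced = row$reduced, competitor = row$competitor)
}

#' Simulate a full session for one participant
#'
#' Runs the practice block and the 96 experimental trials of a session plan
#' through [simulate_trial()]. Per-trial seeds are derived deterministically
#' from `seed` and the trial index, so a session is reproducible
#' bit-identically from `(plan, agent, seed)`.
#'
#' @param plan An `mf_session_plan` from [generate_orders()].
#' @param agent An [agent_profile()].
#' @param geometry,params Task geometry and kinematics.
#' @param seed Integer seed.
#' @param include_practice Whether to simulate and return practice trials.
#' @return A list of `mf_trial_log` objects.
#' @export
simulate_session <- function(plan, agent, geometry = screen_geometry(),
                             params = kinematics_params(), seed = 1L,
                             include_practice = FALSE) {
  rows <- if (include_practice) rbind(plan$practice, plan$trials) else plan$trials
  lapply(seq_len(nrow(rows)), function(i) {
    cfg <- row_config(rows[i, ])
    s <- child_seed(seed, plan$order_id, i + if (rows$is_practice[i]) 1000L else 0L)
    simulate_trial(cfg, geometry, params, agent, seed = s,
                   participant = agent$id)
  })
}

#' Simulate a cohort of participants
#'
#' Assigns session plans to participants cyclically by participant index and
#' simulates every session.
#'
#' @param agents A list of [agent_profile()] (see [make_population()]).
#' @param plans Session plans from [generate_orders()].
#' @param geometry,params Task geometry and kinematics.
#' @param seed Integer seed.
#' @return A list (one element per participant) of lists of `mf_trial_log`.
#' @export
simulate_cohort <- function(agents, plans, geometry = screen_geometry(),
                            params = kinematics_params(), seed = 1L) {
  lapply(seq_along(agents), function(i) {
    plan <- plans[[(i - 1L) %% length(plans) + 1L]]
    simulate_session(plan, agents[[i]], geometry, params,
                     seed = child_seed(seed, i))
  })
}

# columns of the session-log schema, one row per display frame
mf_log_columns <- c(
  "participant", "order_id", "trial_index", "is_practice", "trial_class",
  "target_side", "segment", "reduced", "competitor", "item_id",
  "target_onset_s", "audio_dur_s", "click_time_s", "end_time_s",
  "end_reason", "caught", "host_fps",
  "t", "x", "y", "button", "obj_left_x", "obj_right_x", "obj_y"
)

#' Write / read session logs as delimited text
#'
#' Session logs are stored as a single UTF-8 CSV with a mandatory header,
#' one row per display frame, with the trial metadata repeated on every
#' row (see the package vignette for the schema). `read_session_log()`
#' validates the schema, strictly increasing timestamps within each trial
#' and known condition codes, and reconstructs the list of trial logs;
#' reading back a written file reproduces the logs.
#'
#' @param logs A list of `mf_trial_log` (optionally nested by participant).
#' @param path CSV file path.
#' @return `read_session_log()` returns a list of `mf_trial_log`.
#' @export
write_session_log <- function(logs, path) {
  if (length(logs) && inherits(logs[[1]], "mf_trial_log")) logs <- list(logs)
  tabs <- lapply(unlist(logs, recursive = FALSE), function(log) {
    cfg <- log$config
    f <- log$frames
    data.table::data.table(
      participant = log$participant, order_id = log$order_id %||% NA_integer_,
      trial_index = cfg$trial_index, is_practice = cfg$is_practice,
      trial_class = cfg$trial_class, target_side = cfg$target_side,
      segment = cfg$segment, reduced = cfg$reduced, competitor = cfg$competitor,
      item_id = cfg$item_id, target_onset_s = cfg$target_onset_s,
      audio_dur_s = cfg$audio_dur_s, click_time_s = log$click_time_s,
      end_time_s = log$end_time_s, end_reason = log$end_reason,
      caught = log$caught, host_fps = log$host_fps,
      t = f$t, x = f$x, y = f$y, button = f$button,
      obj_left_x = f$obj_left_x, obj_right_x = f$obj_right_x, obj_y = f$obj_y
    )
  })
  dt <- data.table::rbindlist(tabs)
  # format doubles with 17 significant digits so that reading the file back
  # reproduces the logs bit-identically
  for (col in names(dt)) if (is.double(dt[[col]]))
    data.table::set(dt, j = col,
                    value = ifelse(is.na(dt[[col]]), NA_character_,
                                   sprintf("%.17g", dt[[col]])))
  data.table::fwrite(dt, path, dec = ".", sep = ",", quote = "auto")
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path))
    mf_stop(sprintf("session log not found: %s", path), "mf_io_error")
  dt <- data.table::fread(path, sep = ",", dec = ".", na.strings = c("NA", ""))
  missing_cols <- setdiff(mf_log_columns, names(dt))
  if (length(missing_cols))
    mf_stop(sprintf("session log is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")), "mf_schema_error")
  valid <- list(trial_class = c("critical", "filler_semantic"),
                target_side = c("left", "right"),
                segment = c("h", "glottal"),
                reduced = c("present", "deleted"),
                competitor = c("similar", "different"),
                end_reason = c("click", "audio_tail", "objects_reached_bottom"),
                button = c("up", "down"))
  for (col in names(valid)) {
    vals <- dt[[col]]
    bad <- !is.na(vals) & !vals %in% valid[[col]]
    if (any(bad))
      mf_stop(sprintf("unknown code(s) in column %s: %s", col,
                      paste(unique(vals[bad]), collapse = ", ")),
              "mf_schema_error")
  }
  key <- paste(dt$participant, dt$trial_index, dt$is_practice, sep = "\r")
  split_idx <- split(seq_len(nrow(dt)), factor(key, levels = unique(key)))
  lapply(split_idx, function(idx) {
    rows <- dt[idx]
    if (is.unsorted(rows$t, strictly = TRUE))
      mf_stop(sprintf("non-monotone timestamps in trial %d of participant %s",
                      rows$trial_index[1], rows$participant[1]),
              "mf_integrity_error")
    cfg <- trial_config(
      trial_index = rows$trial_index[1], trial_class = rows$trial_class[1],
      target_side = rows$target_side[1],
      target_onset_s = rows$target_onset_s[1],
      audio_dur_s = rows$audio_dur_s[1], item_id = rows$item_id[1],
      is_practice = rows$is_practice[1], segment = rows$segment[1],
      reduced = rows$reduced[1], competitor = rows$competitor[1])
    structure(
      list(config = cfg, participant = rows$participant[1],
           frames = data.frame(t = rows$t, x = rows$x, y = rows$y,
                               button = rows$button,
                               obj_left_x = rows$obj_left_x,
                               obj_right_x = rows$obj_right_x,
                               obj_y = rows$obj_y),
           click_time_s = rows$click_time_s[1], end_time_s = rows$end_time_s[1],
           end_reason = rows$end_reason[1], caught = rows$caught[1],
           host_fps = rows$host_fps[1]),
      class = "mf_trial_log")
  })
}
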