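#' Categorize an oriented trajectory into the t/l/r/s state string
#'
#' Each grid sample of an oriented trajectory (positive = closer to the
#' target) is categorized as on the target (`'t'`: inside the target
#' corridor, boundaries inclusive), moving toward the target (`'l'`: step
#' from the previous sample larger than `eps`), moving away (`'r'`: step
#' below `-eps`), or stable outside the corridor (`'s'`). The first sample
#' has no predecessor and is `'s'` when outside the corridor. Note `'l'`
#' here always means motion toward the target: trajectories are mirrored
#' before categorization so that the target side is the positive side.
#'
#' @param x Oriented positions (numeric vector) or an `mf_trajectory`.
#' @param corridor Oriented target corridor (closed interval on the
#'   positive side), e.g. `screen_geometry()$corridor_right`.
#' @param eps Stability threshold in screen widths: per-frame steps of
#'   magnitude `eps` or less count as stable (default 1e-3).
#' @return A single character string over `{t,l,r,s}`, one character per
#'   grid point.
#' @export
#' @examples
#' categorize(c(0, 0, 0.1, 0.2, 0.3), corridor = c(0.08, 0.40))
categorize <- function(x, corridor = screen_geometry()$corridor_right,
                       eps = 1e-3) {
  if (inherits(x, "mf_trajectory")) x <- x$x
  inside <- x >= corridor[1] & x <= corridor[2]
  d <- c(0, diff(x))
  states <- rep("s", length(x))
  states[d > eps] <- "l"
  states[d < -eps] <- "r"
  states[1] <- "s"
  states[inside] <- "t"
  paste(states, collapse = "")
}

#' Extract the decision time from a state string
#'
#' The decision time is the start of the last continuous movement that ends
#' inside the target corridor. The latest `"lt"` pair marks the last move
#' into the corridor; from its `'l'` the algorithm walks backwards through
#' the maximal contiguous run of `'l'` states, and the grid time of the
#' run's first `'l'` is the decision time (`source = "lt_backtrack"`). In
#' the rare case of a cursor stable just outside the corridor that enters
#' it within a single frame, the latest `"st"` pair is used instead when it
#' occurs later than the last `"lt"` (or when no `"lt"` exists); the grid
#' time of its `'t'` — the moment of corridor entry — is then the decision
#' time (`source = "st_jump"`).
#'
#' Trials whose cursor was always on the target (an early correct guess)
#' yield `NA` with reason `"always_on_target"`; trials that never reached
#' the corridor — including traces with a `'t'` but no `"lt"` or `"st"`
#' entry pair — yield `NA` with reason `"never_reached_target"`.
#' Negative decision times (commitment before the target onset) are legal,
#' since the grid starts 0.5 s before the onset.
#'
#' @param states A state string from [categorize()].
#' @param grid The [grid_spec()] the string was computed on.
#' @return An `mf_decision` list: `time_s` (or `NA`), `na_reason`
#'   (`"none"`, `"always_on_target"`, `"never_reached_target"`) and
#'   `source` (`"lt_backtrack"`, `"st_jump"` or `NA`).
#' @export
extract_decision_time <- function(states, grid = grid_spec()) {
  s <- strsplit(states, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n != grid$n_points)
    mf_stop("state string length does not match the grid", "mf_parameter_error")
  is_t <- s == "t"
  if (!any(is_t))
    return(mf_decision(NA_real_, "never_reached_target", NA_character_))
  if (all(is_t))
    return(mf_decision(NA_real_, "always_on_target", NA_character_))
  is_l <- s == "l"
  lt <- which(is_l[-n] & is_t[-1])          # positions i with s[i]='l', s[i+1]='t'
  st <- which(s[-n] == "s" & is_t[-1])
  last_lt <- if (length(lt)) lt[length(lt)] else NA_integer_
  last_st <- if (length(st)) st[length(st)] else NA_integer_
  if (!is.na(last_st) && (is.na(last_lt) || last_st > last_lt))
    return(mf_decision(grid$times[last_st + 1L], "none", "st_jump"))
  if (is.na(last_lt))
    return(mf_decision(NA_real_, "never_reached_target", NA_character_))
  j <- last_lt
  while (j > 1L && is_l[j - 1L]) j <- j - 1L
  mf_decision(grid$times[j], "none", "lt_backtrack")
}

mf_decision <- function(time_s, na_reason, source) {
  structure(list(time_s = time_s, na_reason = na_reason, source = source),
            class = "mf_decision")
}

#' Count movement direction changes in a trajectory
#'
#' The number of sign alternations in the sequence of per-sample steps,
#' after discarding steps of magnitude `eps` or less. Used to characterize
#' movement strategies (e.g. clickers vs non-clickers).
#'
#' @param x Positions (numeric vector) or an `mf_trajectory`; orientation
#'   does not affect the count.
#' @param eps Stability threshold (screen widths).
#' @return Integer count of direction changes.
#' @export
count_direction_changes <- function(x, eps = 1e-3) {
  if (inherits(x, "mf_trajectory")) x <- x$x
  d <- diff(x)
  sgn <- sign(d[abs(d) > eps])
  if (length(sgn) < 2L) return(0L)
  sum(sgn[-1] != sgn[-length(sgn)])
}

#' Build the per-trial decision table
#'
#' Applies [categorize()] and [extract_decision_time()] to every
#' preprocessed trajectory and assembles the analysis table.
#'
#' @param pre Result of [preprocess_logs()] (or [read_trajectories()]).
#' @param geometry An [screen_geometry()]; its right corridor is the
#'   oriented target corridor.
#' @param eps Stability threshold (screen widths).
#' @return A `data.frame`: one row per trial with metadata, contrast codes,
#'   `decision_time_s`, `na_reason`, `source`, `n_direction_changes` and
#'   `rt_s` (click time minus target onset, `NA` for unclicked trials).
#' @export
decide_trials <- function(pre, geometry = screen_geometry(), eps = 1e-3) {
  X <- pre$x
  grid <- pre$grid
  n <- nrow(X)
  time_s <- numeric(n); reason <- character(n); source <- character(n)
  dirch <- integer(n)
  corridor <- geometry$corridor_right
  for (i in seq_len(n)) {
    d <- extract_decision_time(categorize(X[i, ], corridor, eps), grid)
    time_s[i] <- d$time_s; reason[i] <- d$na_reason; source[i] <- d$source
    dirch[i] <- count_direction_changes(X[i, ], eps)
  }
  out <- pre$meta
  out$decision_time_s <- time_s
  out$na_reason <- reason
  out$source <- source
  out$n_direction_changes <- dirch
  out$rt_s <- out$click_time_s - out$target_onset_s
  out
}
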