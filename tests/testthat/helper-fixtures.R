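# Shared fixtures and independent oracles for the test suite.

# quick trial configs
mk_critical <- function(onset = 1.2, side = "right", reduced = "present",
                        segment = "h", idx = 1, item = "h01",
                        audio = onset + 1.3) {
  trial_config(idx, "critical", side, onset, audio, item,
               segment = segment, reduced = reduced)
}

mk_filler <- function(onset = 1.2, side = "right", competitor = "different",
                      idx = 1, item = "f01", audio = onset + 1.3) {
  trial_config(idx, "filler_semantic", side, onset, audio, item,
               competitor = competitor)
}

# a deterministic, fast agent for single-trial checks
mk_agent <- function(...) {
  defaults <- list(base_commit_s = 0.4, commit_sd_s = 0, jitter_sd = 0,
                   guess_prob = 0, t_jitter_ms = 0)
  do.call(agent_profile, utils::modifyList(defaults, list(...)))
}

# independent brute-force oracle for decision-time extraction: enumerates
# every index and applies the selection rules literally
oracle_decision <- function(states, grid) {
  v <- strsplit(states, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (!any(v == "t"))
    return(list(time_s = NA_real_, na_reason = "never_reached_target"))
  if (all(v == "t"))
    return(list(time_s = NA_real_, na_reason = "always_on_target"))
  last_lt <- 0L
  last_st <- 0L
  for (i in seq_len(n - 1L)) {
    if (v[i] == "l" && v[i + 1L] == "t") last_lt <- i
    if (v[i] == "s" && v[i + 1L] == "t") last_st <- i
  }
  if (last_st > last_lt)
    return(list(time_s = grid$times[last_st + 1L], na_reason = "none",
                source = "st_jump"))
  if (last_lt == 0L)
    return(list(time_s = NA_real_, na_reason = "never_reached_target"))
  j <- last_lt
  while (j > 1L && v[j - 1L] == "l") j <- j - 1L
  list(time_s = grid$times[j], na_reason = "none", source = "lt_backtrack")
}

# random state strings biased to exercise all branches
random_states <- function(n_points = 151) {
  probs <- list(c(t = 0.4, l = 0.2, r = 0.2, s = 0.2),
                c(t = 0.05, l = 0.3, r = 0.3, s = 0.35),
                c(t = 0.9, l = 0.03, r = 0.03, s = 0.04))
  p <- probs[[sample.int(3, 1)]]
  paste(sample(names(p), n_points, replace = TRUE, prob = p), collapse = "")
}

# hand-built decision-table fixture with known exclusion counts:
# three sub-70% participants, one exactly at the gate, and known numbers of
# early-click / slow / always-on-target trials among the kept participants
screening_fixture <- function() {
  mk <- function(p, n_trials, n_caught, early = 0, slow = 0, aot = 0) {
    caught <- rep(c(TRUE, FALSE), c(n_caught, n_trials - n_caught))
    onset <- rep(1.5, n_trials)
    click <- rep(2.4, n_trials)
    click[seq_len(early)] <- 1.4          # click before the target onset
    end <- rep(3.5, n_trials)
    if (slow > 0) end[early + seq_len(slow)] <- 5.3
    reason <- rep("none", n_trials)
    if (aot > 0) reason[early + slow + seq_len(aot)] <- "always_on_target"
    dt <- ifelse(reason == "none", 0.45, NA_real_)
    data.frame(participant = p, item_id = sprintf("i%02d", seq_len(n_trials)),
               trial_class = "critical", reduced = "present", segment = "h",
               target_onset_s = onset, click_time_s = click, end_time_s = end,
               caught = caught, na_reason = reason, decision_time_s = dt,
               stringsAsFactors = FALSE)
  }
  rbind(mk("low1", 20, 13),                       # 65% < 70%: dropped
        mk("low2", 20, 12),                       # 60%: dropped
        mk("low3", 20, 13, early = 2),            # 65%: dropped
        mk("edge", 20, 14),                       # exactly 70%: kept
        mk("good1", 20, 19, early = 1, slow = 2, aot = 3),
        mk("good2", 20, 18, slow = 1, aot = 1))
}

# simulate a small cohort end-to-end and return the decision table
quick_cohort <- function(n_participants, seed, effect_map, n_orders = 32,
                         clicker_prob = 0.8) {
  inv <- item_inventory(seed = seed)
  plans <- generate_orders(inv, n_orders = n_orders, seed = seed + 1L)
  agents <- make_population(n_participants, seed = seed + 2L,
                            clicker_prob = clicker_prob,
                            effect_map = effect_map)
  logs <- simulate_cohort(agents, plans, seed = seed + 3L)
  decide_trials(preprocess_logs(logs))
}
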