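test_that("state categorization matches a per-sample hand trace", {
  corr <- c(0.08, 0.40)
  # constant outside the corridor: stable throughout
  expect_equal(categorize(rep(-0.2, 6), corr), "ssssss")
  # inside the corridor throughout: all on target
  expect_equal(categorize(rep(0.2, 6), corr), "tttttt")
  # hand-built zigzag, eps = 1e-3:
  x <- c(0.00, 0.00, 0.02, 0.05, 0.03, 0.01, 0.04, 0.09, 0.20, 0.19)
  #      s     s     l     l     r     r     l     t(l)  t     t
  expect_equal(categorize(x, corr), "ssllrrlttt")
  # boundary samples count as inside (closed corridor)
  expect_equal(substr(categorize(c(0, 0.08), corr), 2, 2), "t")
  # steps of magnitude <= eps are stable
  expect_equal(categorize(c(0, 0.001, 0.0021), corr, eps = 1e-3), "ssl")
  # first sample outside the corridor is always 's'
  expect_equal(substr(categorize(c(0.5, 0.49), corr), 1, 1), "s")
})

test_that("decision-time extraction follows the last-move-in rules", {
  g <- grid_spec()
  # always on target: structural data loss
  d <- extract_decision_time(strrep("t", 151), g)
  expect_true(is.na(d$time_s))
  expect_equal(d$na_reason, "always_on_target")
  # never on target
  d2 <- extract_decision_time(strrep("s", 151), g)
  expect_equal(d2$na_reason, "never_reached_target")
  # backtrack through the contiguous 'l' run: "ssrrlllttt" + trailing 't'
  s3 <- paste0("ssrrlll", strrep("t", 144))
  d3 <- extract_decision_time(s3, g)
  expect_equal(d3$source, "lt_backtrack")
  expect_equal(d3$time_s, -0.5 + 4 / 60) # run starts at 0-based index 4
  # stable-to-target jump fallback: "ssss" then 't's, no 'l' anywhere
  s4 <- paste0("ssss", strrep("t", 147))
  d4 <- extract_decision_time(s4, g)
  expect_equal(d4$source, "st_jump")
  expect_equal(d4$time_s, -0.5 + 4 / 60) # the 't' of the 'st' pair
  # an 'st' later than the last 'lt' wins
  s5 <- paste0("lltt", strrep("r", 100), "sst", strrep("t", 44))
  d5 <- extract_decision_time(s5, g)
  expect_equal(d5$source, "st_jump")
  expect_equal(d5$time_s, g$times[107])
  # a 't' with no entry pair at all (starts on target, leaves)
  s6 <- paste0("tt", strrep("r", 10), strrep("s", 139))
  expect_equal(extract_decision_time(s6, g)$na_reason, "never_reached_target")
})

test_that("extraction agrees with the brute-force oracle on random strings", {
  g <- grid_spec()
  set.seed(303)
  for (i in 1:1000) {
    s <- random_states()
    got <- extract_decision_time(s, g)
    want <- oracle_decision(s, g)
    expect_identical(got$time_s, want$time_s)
    expect_identical(got$na_reason, want$na_reason)
  }
})

test_that("direction changes count eps-thresholded sign alternations", {
  expect_equal(count_direction_changes(seq(0, 0.5, by = 0.01)), 0L)
  expect_equal(count_direction_changes(rep(0.2, 50)), 0L)
  # steps +,+,-,+,- above eps: three alternations
  x <- cumsum(c(0, 0.01, 0.01, -0.01, 0.01, -0.01))
  expect_equal(count_direction_changes(x), 3L)
  # sub-eps wobble between large steps is ignored
  x2 <- cumsum(c(0, 0.01, 0.0005, -0.0005, 0.01))
  expect_equal(count_direction_changes(x2, eps = 1e-3), 0L)
})

test_that("decision time responds monotonically to later commitments", {
  g <- grid_spec()
  times <- numeric(8)
  for (k in seq_len(8)) {
    commit <- 0.3 + (k - 1) / 60
    ag <- mk_agent(base_commit_s = commit, is_clicker = FALSE)
    log <- simulate_trial(mk_critical(onset = 1.0, audio = 2.2),
                          agent = ag, seed = 7)
    tr <- orient(regrid(log$frames, 1.0, g), "right")
    times[k] <- extract_decision_time(categorize(tr$x), g)$time_s
  }
  expect_true(all(diff(times) >= 0))
})
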