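test_that("fall duration guarantees the post-onset window", {
  expect_equal(adjust_fall_duration(0.73, 3, 2), 3)
  expect_equal(adjust_fall_duration(3.26, 3, 2), 5.26)
  expect_equal(adjust_fall_duration(1.0, 3, 2), 3)
  expect_error(adjust_fall_duration(-1, 3, 2), class = "mf_parameter_error")
  # property: the window holds over the whole onset range (up to double
  # rounding in the subtraction)
  onsets <- seq(0.73, 3.26, length.out = 200)
  expect_true(all(adjust_fall_duration(onsets, 3, 2) - onsets >= 2 - 1e-9))
})

test_that("object stepping flips at the boundary and at the draw", {
  corr <- c(0.08, 0.40)
  st <- object_state(x = 0.40, y = 0.9, dir = 1, speed_x = 0.01,
                    speed_y = 0.001, corridor = corr)
  out <- step_object(st, u = 0.9)  # boundary flip despite a large draw
  expect_equal(out$dir, -1)
  expect_equal(out$x, 0.39)
  mid <- object_state(x = 0.2, y = 0.9, dir = 1, speed_x = 0.01,
                      speed_y = 0.001, corridor = corr)
  expect_equal(step_object(mid, u = 0.5)$dir, 1)   # u >= 1/40: no flip
  expect_equal(step_object(mid, u = 0.01)$dir, -1) # u < 1/40: flip
  expect_equal(step_object(mid, u = 0.5)$y, 0.9 - 0.001)
})

test_that("empirical interior flip frequency matches the binomial rate", {
  set.seed(802)
  n <- 1e5
  u <- runif(n)
  # interior steps only: a wide corridor and a tiny step never hit the wall
  st <- object_state(0.2, 0.9, 1, 1e-9, 0, c(0.08, 0.40))
  flips <- 0L
  for (i in seq_len(n)) {
    new <- step_object(st, u[i])
    if (new$dir != st$dir) flips <- flips + 1L
    st <- new
  }
  p <- 1 / 40
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(flips / n - p), 3 * se)
})

test_that("catch adjudication is strict at the 5% tolerance", {
  expect_true(adjudicate_catch(0.10, 0.14, 0.05))
  expect_false(adjudicate_catch(0, 0.05, 0.05)) # exactly at the bound
  expect_false(adjudicate_catch(0.10, 0.16, 0.05))
  expect_true(adjudicate_catch(0.3, 0.3, 0.05))
})

test_that("trial termination follows the click/audio/fall rules", {
  # never-clicking agent: routine ends when objects reach the bottom
  cfg <- mk_critical(onset = 1.0, audio = 2.0)
  log <- simulate_trial(cfg, agent = mk_agent(is_clicker = FALSE), seed = 5)
  expect_equal(log$end_reason, "objects_reached_bottom")
  expect_equal(log$end_time_s, adjust_fall_duration(1.0, 3, 2))
  expect_true(all(log$frames$t <= log$end_time_s))

  # click during the audio: routine ends 200 ms after the sound finished
  cfg2 <- mk_critical(onset = 0.8, audio = 2.5)
  log2 <- simulate_trial(cfg2, agent = mk_agent(base_commit_s = 0.3), seed = 5)
  expect_lt(log2$click_time_s, cfg2$audio_dur_s)
  expect_equal(log2$end_reason, "audio_tail")
  expect_equal(log2$end_time_s, cfg2$audio_dur_s + 0.2)

  # click after the audio ended: routine ends 200 ms after the click
  cfg3 <- mk_critical(onset = 2.2, audio = 2.4)
  log3 <- simulate_trial(cfg3, agent = mk_agent(base_commit_s = 0.5), seed = 5)
  expect_gt(log3$click_time_s, cfg3$audio_dur_s)
  expect_equal(log3$end_reason, "click")
  expect_equal(log3$end_time_s, log3$click_time_s + 0.2)
})

test_that("a trial and its mirrored twin are exact negations under one seed", {
  cfg <- mk_critical(side = "right")
  a <- simulate_trial(cfg, agent = mk_agent(jitter_sd = 0.003), seed = 77)
  b <- simulate_trial(mirror_trial_config(cfg),
                      agent = mk_agent(jitter_sd = 0.003), seed = 77)
  expect_equal(b$frames$x, -a$frames$x)
  expect_equal(b$frames$obj_left_x, -a$frames$obj_right_x)
  expect_equal(b$frames$obj_right_x, -a$frames$obj_left_x)
  expect_identical(b$frames$t, a$frames$t)
  expect_identical(b$caught, a$caught)
})

test_that("trial logs are bit-identical reproductions of (config, seed)", {
  cfg <- mk_filler(onset = 2.1, competitor = "similar")
  ag <- agent_profile(host_fps = 75, t_jitter_ms = 1)
  a <- simulate_trial(cfg, agent = ag, seed = 31)
  b <- simulate_trial(cfg, agent = ag, seed = 31)
  expect_identical(a$frames, b$frames)
  expect_identical(a$caught, b$caught)
  c <- simulate_trial(cfg, agent = ag, seed = 32)
  expect_false(identical(a$frames$x, c$frames$x))
})

test_that("objects stay inside their corridors and animations freeze at the click", {
  geom <- screen_geometry()
  for (s in 1:50) {
    cfg <- mk_critical(onset = runif(1, 0.73, 3.26))
    log <- simulate_trial(cfg, agent = mk_agent(jitter_sd = 0.003), seed = s)
    f <- log$frames
    expect_true(all(f$obj_left_x >= geom$corridor_left[1] &
                      f$obj_left_x <= geom$corridor_left[2]))
    expect_true(all(f$obj_right_x >= geom$corridor_right[1] &
                      f$obj_right_x <= geom$corridor_right[2]))
    expect_true(all(diff(f$obj_y) <= 1e-12))
    if (!is.na(log$click_time_s)) {
      after <- f$t > log$click_time_s
      if (sum(after) > 1) {
        expect_equal(length(unique(f$obj_right_x[after])), 1L)
        expect_equal(length(unique(f$obj_y[after])), 1L)
      }
    }
  }
})
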