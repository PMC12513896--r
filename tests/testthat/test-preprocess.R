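test_that("the analysis grid has exactly 151 points at 16.67 ms spacing", {
  g <- grid_spec()
  expect_equal(g$n_points, 151L)
  expect_equal(length(g$times), 151L)
  expect_equal(g$times[1], -0.5)
  expect_equal(g$times[151], 2.0)
  expect_equal(unique(round(diff(g$times), 10)), round(1 / 60, 10))
})

test_that("regridding picks the nearest sample with ties to the earlier one", {
  # frames exactly on the grid: identity
  g <- grid_spec()
  onset <- 1.0
  x <- runif(151, -0.5, 0.5)
  frames <- data.frame(t = onset + g$times, x = x)
  expect_equal(regrid(frames, onset, g)$x, x)

  # single frame: constant trajectory, padding from the slot after it
  one <- data.frame(t = 1.0, x = 0.2)
  tr <- regrid(one, 1.0, g)
  expect_equal(tr$x, rep(0.2, 151))
  expect_equal(tr$pad_from, 32L) # grid index 31 is t = 0; padding starts after

  # tie rule: a grid point exactly halfway takes the earlier sample
  gg <- grid_spec(t_start = 0.0125, t_end = 0.0125, rate = 60)
  expect_equal(gg$n_points, 1L)
  frames2 <- data.frame(t = c(0, 0.025), x = c(-0.1, 0.3))
  expect_equal(regrid(frames2, 0, gg)$x, -0.1)

  expect_error(regrid(data.frame(t = numeric(0), x = numeric(0)), 1),
               class = "mf_preprocessing_error")
})

test_that("output length is 151 for every host frame rate", {
  for (fps in c(30, 60, 75, 144)) {
    ag <- agent_profile(host_fps = fps, t_jitter_ms = 1)
    log <- simulate_trial(mk_critical(onset = 1.4), agent = ag, seed = fps)
    tr <- regrid(log$frames, 1.4)
    expect_length(tr$x, 151L)
    expect_true(all(is.finite(tr$x)))
    expect_true(all(abs(tr$x) <= 0.5))
  }
})

test_that("orientation flips left-target trajectories and is an involution", {
  g <- grid_spec()
  tr <- regrid(data.frame(t = 1 + g$times, x = seq(-0.2, 0.3, length.out = 151)), 1)
  expect_equal(orient(tr, "right")$x, tr$x)
  expect_equal(orient(tr, "left")$x[1], 0.2)
  for (i in 1:20) {
    x <- runif(151, -0.5, 0.5)
    tr$x <- x
    expect_equal(orient(orient(tr, "left"), "left")$x, x)
  }
})

test_that("regridding commutes with mirroring", {
  set.seed(55)
  t <- cumsum(runif(80, 0.01, 0.02))
  x <- cumsum(rnorm(80, 0, 0.01))
  a <- regrid(data.frame(t = t, x = x), 0.6)
  b <- regrid(data.frame(t = t, x = -x), 0.6)
  expect_equal(b$x, -a$x)
  expect_equal(b$pad_from, a$pad_from)
})

test_that("downsampling changes regridded positions by less than one cursor step", {
  # a constant-slope cursor ramp logged at 144 fps vs every third frame (48 fps)
  slope <- 0.3
  t144 <- seq(0, 2.5, by = 1 / 144)
  x144 <- -0.4 + slope * t144
  keep <- seq(1, length(t144), by = 3)
  g <- grid_spec(t_start = 0, t_end = 2, rate = 60)
  hi <- regrid(data.frame(t = t144, x = x144), 0, g)
  lo <- regrid(data.frame(t = t144[keep], x = x144[keep]), 0, g)
  max_step_48 <- max(abs(diff(x144[keep])))
  expect_lt(max(abs(hi$x - lo$x)), max_step_48)
})

test_that("bulk preprocessing orients trajectories and keeps metadata aligned", {
  inv <- item_inventory(seed = 61)
  plan <- generate_orders(inv, 2, seed = 62)[[1]]
  logs <- simulate_session(plan, agent_profile(id = "p01"), seed = 63)[1:12]
  pre <- preprocess_logs(logs)
  expect_equal(dim(pre$x), c(12L, 151L))
  expect_equal(nrow(pre$meta), 12L)
  # oriented: late positions are mostly on the positive (target) side
  expect_gt(mean(pre$x[, 140:151] > 0), 0.7)
  deleted <- which(pre$meta$reduced == "deleted")
  if (length(deleted))
    expect_equal(pre$meta$reductionC[deleted[1]], -0.5)
  expect_true(all(is.na(pre$meta$predictabilityC[pre$meta$trial_class == "critical"])))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(pre, path)
  back <- read_trajectories(path)
  expect_equal(back$x, pre$x)
  expect_equal(back$meta$item_id, pre$meta$item_id)
  expect_equal(back$grid$n_points, 151L)
})
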