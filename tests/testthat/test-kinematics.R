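fit_amplitude <- function(y, f, fs) {
  n <- length(y)
  mid <- seq(floor(n / 3), ceiling(2 * n / 3))
  t <- (mid - 1) / fs
  co <- coef(lm(y[mid] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

test_that("zero-lag filter has unit DC gain and the analytic attenuation", {
  fs <- 300
  expect_equal(zero_lag_lowpass(rep(3.7, 400), fs), rep(3.7, 400))
  t <- (0:1799) / fs
  # 1 Hz well below the 6 Hz cut-off: amplitude preserved within 1%
  y1 <- zero_lag_lowpass(sin(2 * pi * 1 * t), fs)
  expect_equal(unname(fit_amplitude(y1, 1, fs)), 1, tolerance = 0.01)
  # at the cut-off the zero-phase gain is the squared single-pass half-power
  y6 <- zero_lag_lowpass(sin(2 * pi * 6 * t), fs)
  expect_equal(unname(fit_amplitude(y6, 6, fs)), 0.5, tolerance = 0.01)
  expect_error(zero_lag_lowpass(sin(t), 11, cutoff = 6), "exceed")
  expect_error(zero_lag_lowpass(rnorm(10), 300), "too short")
})

test_that("the filter is zero-phase: no lag on a passband sinusoid", {
  fs <- 300
  t <- (0:1799) / fs
  x <- sin(2 * pi * 2 * t)
  y <- zero_lag_lowpass(x, fs)
  cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("refiltering an already-filtered angle series barely moves RoM", {
  ex <- extract_one_trial(std_profile(), noise_sd = 1, seed = 3)
  a <- joint_angle_series(ex$trf, "hip", "left")
  r1 <- range_of_motion(a, ex$win)
  a$angle <- zero_lag_lowpass(a$angle, 300)
  r2 <- range_of_motion(a, ex$win)
  expect_lt(abs(r1 - r2), 0.1)
})

test_that("gap interpolation fills short gaps exactly and rejects long ones", {
  tr <- generate_trial(std_profile(), noise_sd = 0, seed = 1)$traj
  expect_identical(interpolate_gaps(tr)$markers, tr$markers)
  # a 3-frame gap inside a linear ramp is restored exactly
  tr2 <- tr
  truth <- tr2$markers$sacrum[101:103, ]
  tr2$markers$sacrum[101:103, ] <- NA
  filled <- interpolate_gaps(tr2)
  expect_equal(filled$markers$sacrum[101:103, 2], truth[, 2], tolerance = 1e-2)
  expect_equal(filled$markers$sacrum[100, ], tr$markers$sacrum[100, ])
  # 0.2 s gap (60 frames at 300 Hz) -> trial rejected
  tr3 <- tr
  tr3$markers$sacrum[101:160, ] <- NA
  expect_error(interpolate_gaps(tr3), "excluded")
})

test_that("events are detected at the true frames on noise-free gait", {
  tr <- generate_trial(std_profile(), noise_sd = 0, seed = 1)
  ev <- detect_gait_events(filter_markers(tr$traj))
  for (side in c("left", "right")) {
    expect_true(all(event_errors(ev[[side]]$heel_strike,
                                 tr$events[[side]]$heel_strike) <= 3))
    expect_true(all(event_errors(ev[[side]]$toe_off,
                                 tr$events[[side]]$toe_off) <= 3))
  }
})

test_that("events stay within 6 frames of truth under 1 mm marker noise", {
  errs <- unlist(lapply(1:50, function(sd) {
    tr <- generate_trial(std_profile(), noise_sd = 1, seed = sd)
    ev <- detect_gait_events(filter_markers(tr$traj))
    c(event_errors(ev$left$heel_strike, tr$events$left$heel_strike),
      event_errors(ev$right$toe_off, tr$events$right$toe_off))
  }))
  expect_true(all(errs <= 6))
})

test_that("event detection is invariant to walking direction", {
  tr <- generate_trial(std_profile(), noise_sd = 0, seed = 4)
  ev1 <- detect_gait_events(filter_markers(tr$traj))
  rev_traj <- tr$traj
  rev_traj$markers <- lapply(rev_traj$markers, function(m) {
    m[, 2] <- -m[, 2]; m
  })
  ev2 <- detect_gait_events(filter_markers(rev_traj))
  expect_identical(ev1$left$heel_strike, ev2$left$heel_strike)
  expect_identical(ev1$right$toe_off, ev2$right$toe_off)
})

test_that("accepted trials satisfy the per-side event alternation invariant", {
  for (sd in 1:5) {
    tr <- generate_trial(std_profile(cadence = 90 + 10 * sd), noise_sd = 1,
                         seed = sd)
    ev <- detect_gait_events(filter_markers(tr$traj))
    for (side in c("left", "right")) {
      hs <- ev[[side]]$heel_strike; to <- ev[[side]]$toe_off
      expect_true(all(diff(hs) > 0) && all(diff(to) > 0))
      # every toe-off falls strictly between consecutive heel strikes
      expect_equal(length(to), length(hs) - 1)
      expect_true(all(to > head(hs, -1) & to < tail(hs, -1)))
    }
  }
})

test_that("steady-state selection implements the trial/step policy", {
  # 6 trials x 7 steps/side -> first trial dropped, central 2 steps per side
  # of the 5 remaining trials: 20 windows
  sel <- select_steady_state(rep(list(make_events(7)), 6))
  expect_equal(nrow(sel$windows), 20)
  expect_equal(unique(sel$windows$trial), 2:6)
  expect_length(sel$exclusions, 0)
  # too few trials is a hard error
  expect_error(select_steady_state(rep(list(make_events(7)), 5)), "at least 6")
  # a trial with < 6 steps per side cannot yield central steps: excluded
  sel2 <- select_steady_state(c(list(make_events(7)), rep(list(make_events(5)), 5)))
  expect_equal(nrow(sel2$windows), 0)
  expect_length(sel2$exclusions, 5)
})

test_that("an odd usable-step count ties toward the later central pair", {
  # 9 steps/side: trim 2+2 leaves 5 usable (indices 3..7); the central pair
  # must be the later one (steps 5 and 6 of the side)
  sel <- select_steady_state(rep(list(make_events(9)), 6))
  for (side in c("left", "right")) {
    idx <- sel$windows$step_index[sel$windows$trial == 2 &
                                    sel$windows$side == side]
    expect_equal(idx, c(5, 6))
  }
})

test_that("extracted joint and trunk RoMs match the generating profile", {
  p <- std_profile()
  ex <- extract_one_trial(p, noise_sd = 0, seed = 6)
  expect_equal(unname(ex$rom["hip_left"]), 33, tolerance = 0.5 / 33)
  expect_equal(unname(ex$rom["knee_right"]), 48, tolerance = 0.5 / 48)
  expect_equal(unname(ex$rom["ankle_left"]), 24, tolerance = 0.5 / 24)
  # trunk transverse oscillation of +/- 3.5 deg -> RoM 7.0 +/- 0.2
  expect_equal(unname(ex$rom["trunk_transverse"]), 7, tolerance = 0.2 / 7)
  expect_equal(unname(ex$rom["trunk_sagittal"]), 3.5, tolerance = 0.2 / 3.5)
})

test_that("range of motion follows its closed forms and window subsetting", {
  s <- structure(list(angle = rep(2, 100), joint = "hip", side = "left",
                      plane = "sagittal"), class = "joint_angle_series")
  expect_equal(range_of_motion(s), 0)
  a <- 3.7
  s$angle <- a * sin(seq(0, 4 * pi, length.out = 1000))
  expect_equal(range_of_motion(s), 2 * a, tolerance = 1e-4)
  # windowed RoM on a drifting signal never exceeds the full-trial RoM
  s$angle <- sin(seq(0, 4 * pi, length.out = 1000)) +
    seq(0, 5, length.out = 1000)
  win <- data.frame(start_frame = 200, end_frame = 400)
  expect_lte(range_of_motion(s, win), range_of_motion(s))
  expect_error(range_of_motion(s, win[0, ]), "empty")
})

test_that("degenerate segments and missing markers raise errors", {
  tr <- generate_trial(std_profile(), noise_sd = 0, seed = 1)$traj
  tr$markers$l_knee <- tr$markers$l_malleolus  # zero-length shank
  expect_error(joint_angle_series(tr, "knee", "left"), "degenerate")
  tr2 <- generate_trial(std_profile(), noise_sd = 0, seed = 1)$traj
  tr2$markers$sacrum <- NULL
  expect_error(detect_gait_events(tr2), "sacrum")
  expect_error(joint_angle_series(
    generate_trial(std_profile(), noise_sd = 0, seed = 1)$traj,
    "hip", "left", "frontal"), "sagittal")
})
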