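# shared fixtures, built in code

std_profile <- function(step_a = 0.5, step_na = 0.5, cadence = 100,
                        stance = 62, ...) {
  gait_profile(step_a, step_na, cadence = cadence, stance_pct = stance,
               step_width = 0.16, hip_rom = 33, knee_rom = 48,
               ankle_rom = 24, trunk_rom = c(3.5, 4, 7), ...)
}

# generate one trial, run the measurement chain, return extracted quantities
extract_one_trial <- function(profile, noise_sd = 0, seed = 1,
                              n_strides = 8, affected_side = "left") {
  tr <- generate_trial(profile, n_strides = n_strides, noise_sd = noise_sd,
                       seed = seed, affected_side = affected_side)
  trf <- filter_markers(tr$traj)
  ev <- detect_gait_events(trf)
  sel <- select_steady_state(rep(list(ev), 6))
  win <- sel$windows[sel$windows$trial == 2, ]
  st <- spatiotemporal(ev, trf, win)
  rom <- c(
    hip_left = range_of_motion(joint_angle_series(trf, "hip", "left"), win),
    hip_right = range_of_motion(joint_angle_series(trf, "hip", "right"), win),
    knee_left = range_of_motion(joint_angle_series(trf, "knee", "left"), win),
    knee_right = range_of_motion(joint_angle_series(trf, "knee", "right"), win),
    ankle_left = range_of_motion(joint_angle_series(trf, "ankle", "left"), win),
    ankle_right = range_of_motion(joint_angle_series(trf, "ankle", "right"), win),
    trunk_sagittal = range_of_motion(
      joint_angle_series(trf, "trunk", "none", "sagittal"), win),
    trunk_frontal = range_of_motion(
      joint_angle_series(trf, "trunk", "none", "frontal"), win),
    trunk_transverse = range_of_motion(
      joint_angle_series(trf, "trunk", "none", "transverse"), win))
  list(trial = tr, trf = trf, ev = ev, win = win, st = st, rom = rom)
}

# synthetic gait_events with k heel strikes per side at a fixed stride
make_events <- function(n_steps_per_side, stride = 100, stance_frac = 0.62,
                        fs = 100) {
  hs_l <- 1 + stride * (0:n_steps_per_side)
  hs_r <- 1 + stride %/% 2 + stride * (0:(n_steps_per_side - 1))
  structure(list(
    left = list(heel_strike = hs_l,
                toe_off = head(hs_l, -1) + round(stance_frac * stride)),
    right = list(heel_strike = hs_r,
                 toe_off = head(hs_r, -1) + round(stance_frac * stride)),
    sampling_rate = fs, n_frames = max(hs_l, hs_r) + stride),
    class = "gait_events")
}

# nearest-event absolute frame error, ignoring truth events the detector
# cannot see (trial-boundary events)
event_errors <- function(detected, truth) {
  vapply(detected, function(f) min(abs(truth - f)), numeric(1))
}
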