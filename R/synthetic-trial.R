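#' Generate one synthetic walking trial
#'
#' Forward model of an overground walking trial for the package's 13-marker
#' set. Foot markers follow an explicit footfall schedule (heel strikes and
#' toe-offs at known times, feet stationary during stance, smooth swing
#' transport), so spatio-temporal ground truth is exact; pelvis, leg-chain
#' and trunk markers are driven by two-harmonic joint-angle templates scaled
#' to the profile's RoMs through a sagittal two-segment-per-leg kinematic
#' chain. Ground-truth event frames and the generating profile are returned
#' alongside the trajectories.
#'
#' The swing-phase transport uses a velocity template with non-zero lift-off
#' and touch-down velocity (about twice the average progression speed), so
#' the anterior heel/toe positions relative to the sacrum have sharp, well
#' defined extrema exactly at the true events; this keeps coordinate-based
#' event detection identifiable even after low-pass filtering.
#'
#' @param profile a [gait_profile()].
#' @param n_strides number of strides (>= 5 so steady-state selection can
#'   discard two steps at each end).
#' @param sampling_rate sampling frequency in Hz (default 300).
#' @param noise_sd additive white Gaussian marker noise, mm (default 1).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @param affected_side which side carries `step_length_a` ("left"/"right").
#' @param trial_id trial identifier.
#' @return list with `traj` (a `marker_trajectory_set`), `events` (true
#'   per-side heel-strike/toe-off frame indices, 1-based), `profile`, and
#'   `truth` (per-side step lengths, stance/double-support \%, stride time).
#' @export
generate_trial <- function(profile, n_strides = 8, sampling_rate = 300,
                           noise_sd = 1, seed = NULL,
                           affected_side = c("left", "right"),
                           trial_id = "trial") {
  stopifnot(inherits(profile, "gait_profile"))
  affected_side <- match.arg(affected_side)
  if (n_strides < 5) stop("n_strides must be >= 5")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  mdl <- gait_marker_model()

  TT <- 120 / profile$cadence               # stride duration (s)
  # map A/NA onto left/right
  if (affected_side == "left") {
    s_left <- profile$step_length_a * 1000;  s_right <- profile$step_length_na * 1000
    st_left <- profile$stance_pct[1];        st_right <- profile$stance_pct[2]
    rom_l <- c(profile$hip_rom[1], profile$knee_rom[1], profile$ankle_rom[1])
    rom_r <- c(profile$hip_rom[2], profile$knee_rom[2], profile$ankle_rom[2])
  } else {
    s_right <- profile$step_length_a * 1000; s_left <- profile$step_length_na * 1000
    st_right <- profile$stance_pct[1];       st_left <- profile$stance_pct[2]
    rom_r <- c(profile$hip_rom[1], profile$knee_rom[1], profile$ankle_rom[1])
    rom_l <- c(profile$hip_rom[2], profile$knee_rom[2], profile$ankle_rom[2])
  }
  stride_len <- s_left + s_right            # mm
  v <- profile$speed * 1000                 # mm/s
  t_end <- n_strides * TT + 0.25 * TT
  n <- floor(t_end * sampling_rate) + 1
  t <- (seq_len(n) - 1) / sampling_rate
  w <- 2 * pi / TT

  # footfall schedule: left HS at k*TT (k = 0..n_strides), right HS at
  # k*TT + TT/2; toe-off a stance-fraction later.
  hs_left  <- TT * (0:n_strides)
  hs_right <- TT * (0:(n_strides - 1)) + TT / 2
  to_left  <- hs_left + st_left / 100 * TT
  to_right <- c(hs_right[1] - TT, hs_right) + st_right / 100 * TT # incl. pre-trial stride
  y_left  <- stride_len * (0:n_strides)                 # footfall positions (mm)
  y_right <- s_right + stride_len * (0:(n_strides - 1))

  # swing transport: velocity c + (1-c) sin(pi u), c set so lift-off/landing
  # velocity is ~2x the mean progression speed (clamped), displacement 1.
  swing_frac <- 1 - (st_left + st_right) / 200
  cc <- min(0.9, max(0.15, 1.27324 * swing_frac / (1 - 0.72676 * swing_frac)))
  s_curve <- function(u) {
    (cc * u + (1 - cc) * (1 - cos(pi * u)) / pi) / (cc + (1 - cc) * 2 / pi)
  }

  foot_path <- function(hs, to_all, y_hs, y0_pre) {
    # anterior position and swing phase u(t) for one foot
    y <- numeric(n); u <- numeric(n)
    to_pre <- to_all[1]; tos <- to_all[-1]   # toe-off of pre-trial stance
    for (i in seq_len(n)) {
      ti <- t[i]
      k <- findInterval(ti, hs)              # completed heel strikes
      if (k == 0) {                          # before first HS of this foot
        if (ti <= to_pre) { y[i] <- y0_pre } else {
          uu <- (ti - to_pre) / (hs[1] - to_pre)
          y[i] <- y0_pre + (y_hs[1] - y0_pre) * s_curve(uu); u[i] <- uu
        }
      } else if (k >= length(hs)) {          # after last HS: stand
        y[i] <- y_hs[length(hs)]
      } else {
        to_k <- tos[k]
        if (ti <= to_k) { y[i] <- y_hs[k] } else {
          uu <- (ti - to_k) / (hs[k + 1] - to_k)
          y[i] <- y_hs[k] + (y_hs[k + 1] - y_hs[k]) * s_curve(uu); u[i] <- uu
        }
      }
    }
    list(y = y, u = u)
  }
  # the left foot's first heel strike opens the trial, so a dummy pre-trial
  # toe-off keeps its per-stride toe-offs aligned
  fl <- foot_path(hs_left, c(-1, to_left), y_left, y_left[1] - stride_len)
  fr <- foot_path(hs_right, to_right, y_right, y_right[1] - stride_len)

  wd2 <- profile$step_width * 1000 / 2
  heel_l_x <- rep(-wd2, n); heel_r_x <- rep(wd2, n)
  heel_l_z <- mdl$heel_height + mdl$swing_lift * sin(pi * fl$u)
  heel_r_z <- mdl$heel_height + mdl$swing_lift * sin(pi * fr$u)

  # sacrum: constant progression + stride-periodic oscillations (periodic at
  # the stride frequency so anterior phase cancels over whole strides)
  sac_y <- -s_left / 2 + v * t + 3 * sin(w * t + 0.4)
  sac_x <- 15 * sin(w * t)
  sac_z <- mdl$pelvis_height + 10 * sin(2 * w * t + 1.1)
  pelvis_yaw <- (4 * pi / 180) * sin(w * t + 0.2)

  rot_xy <- function(x, y, psi) list(x = x * cos(psi) - y * sin(psi),
                                     y = x * sin(psi) + y * cos(psi))
  place_pelvis <- function(off, side_sign) {
    r <- rot_xy(side_sign * off[1], off[2], pelvis_yaw)
    cbind(sac_x + r$x, sac_y + r$y, sac_z + off[3])
  }
  l_asis <- place_pelvis(mdl$asis_offset, -1)
  r_asis <- place_pelvis(mdl$asis_offset, +1)
  hip_l <- place_pelvis(mdl$hip_offset, -1)
  hip_r <- place_pelvis(mdl$hip_offset, +1)

  # joint-angle templates (deg). Right side leads by half a stride.
  leg_angles <- function(rom, phase) {
    hip   <- harmonic_curve(t, TT, rom[1], mean = 5,  phase = phase,        a2 = 0.20, p2 = 0.6)
    knee  <- harmonic_curve(t, TT, rom[2], mean = 28, phase = phase - 0.7,  a2 = 0.45, p2 = -1.2)
    ankle <- harmonic_curve(t, TT, rom[3], mean = 0,  phase = phase + 1.1,  a2 = 0.35, p2 = 2.0)
    list(hip = hip, knee = knee, ankle = ankle)
  }
  al <- leg_angles(rom_l, phase = 0)
  ar <- leg_angles(rom_r, phase = pi)
  d2r <- pi / 180

  chain <- function(hip_c, ang, heel_y, heel_z, heel_x) {
    th <- ang$hip * d2r                 # thigh angle from vertical
    ts <- (ang$hip - ang$knee) * d2r    # shank angle from vertical
    knee <- cbind(hip_c[, 1],
                  hip_c[, 2] + mdl$thigh_length * sin(th),
                  hip_c[, 3] - mdl$thigh_length * cos(th))
    mall <- cbind(knee[, 1],
                  knee[, 2] + mdl$shank_length * sin(ts),
                  knee[, 3] - mdl$shank_length * cos(ts))
    # foot pitch chosen so the shank-vs-foot angle equals the ankle template
    phi <- ts + ang$ankle * d2r
    toe <- cbind(heel_x,
                 heel_y + mdl$foot_length * cos(phi),
                 heel_z + mdl$foot_length * sin(phi))
    list(knee = knee, mall = mall, toe = toe)
  }
  cl <- chain(hip_l, al, fl$y, heel_l_z, heel_l_x)
  cr <- chain(hip_r, ar, fr$y, heel_r_z, heel_r_x)

  # trunk: pitch (sagittal, twice per stride), roll (frontal), yaw (transverse)
  pitch <- harmonic_curve(t, TT / 2, profile$trunk_rom[1], mean = 3, phase = 0.3,
                          a2 = 0.15, p2 = 0.2) * d2r
  roll  <- harmonic_curve(t, TT, profile$trunk_rom[2], mean = 0, phase = 1.0,
                          a2 = 0.10, p2 = 0.5) * d2r
  yaw_t <- harmonic_curve(t, TT, profile$trunk_rom[3], mean = 0, phase = 0.2 + pi,
                          a2 = 0.10, p2 = 0.0) * d2r
  tdir <- cbind(sin(roll) * cos(pitch), sin(pitch), cos(roll) * cos(pitch))
  c7 <- cbind(sac_x, sac_y, sac_z) + mdl$trunk_length * tdir
  acr <- function(side_sign) {
    r <- rot_xy(side_sign * mdl$acromion_offset[1], mdl$acromion_offset[2], yaw_t)
    cbind(c7[, 1] + r$x, c7[, 2] + r$y, c7[, 3] + mdl$acromion_offset[3])
  }

  markers <- list(
    sacrum = cbind(sac_x, sac_y, sac_z),
    l_asis = l_asis, r_asis = r_asis,
    l_knee = cl$knee, r_knee = cr$knee,
    l_malleolus = cl$mall, r_malleolus = cr$mall,
    l_heel = cbind(heel_l_x, fl$y, heel_l_z),
    r_heel = cbind(heel_r_x, fr$y, heel_r_z),
    l_toe = cl$toe, r_toe = cr$toe,
    l_acromion = acr(-1), r_acromion = acr(+1),
    c7 = c7
  )
  markers <- lapply(markers, function(m) {
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    if (noise_sd > 0) m + matrix(rnorm(length(m), 0, noise_sd), nrow(m), 3) else m
  })

  to_frame <- function(x) round(x * sampling_rate) + 1
  in_trial <- function(x) x[x >= 0 & x <= t[n]]
  events <- list(
    left  = list(heel_strike = to_frame(in_trial(hs_left)),
                 toe_off     = to_frame(in_trial(to_left))),
    right = list(heel_strike = to_frame(in_trial(hs_right)),
                 toe_off     = to_frame(in_trial(to_right[-1])))
  )
  truth <- list(
    step_length = c(left = s_left / 1000, right = s_right / 1000),
    stance_pct = c(left = st_left, right = st_right),
    double_support_pct = c(left = st_right - 50, right = st_left - 50),
    stride_time = TT, affected_side = affected_side
  )
  list(traj = marker_trajectory_set(trial_id, sampling_rate, markers),
       events = events, profile = profile, truth = truth)
}
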