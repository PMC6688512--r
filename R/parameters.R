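#' Spatial asymmetry index
#'
#' `100 * (1 - min(a, b) / max(a, b))` between the step lengths of the two
#' sides. The index is symmetric in its arguments, zero only for equal
#' steps, and lies in \[0, 100).
#'
#' @param a_step,na_step step lengths (m) of the affected/most-affected and
#'   unaffected/least-affected sides; both must be positive.
#' @return asymmetry in percent.
#' @examples
#' spatial_asymmetry(0.30, 0.40)  # 25
#' @export
spatial_asymmetry <- function(a_step, na_step) {
  if (any(!is.finite(c(a_step, na_step))) || any(c(a_step, na_step) <= 0))
    stop("step lengths must be finite and positive")
  100 * (1 - pmin(a_step, na_step) / pmax(a_step, na_step))
}

#' Per-trial spatio-temporal parameters
#'
#' Computes, over the retained step windows of one trial: per-step step
#' length (anterior distance between contralateral heel positions at
#' successive heel strikes, m) and step width (mediolateral distance at the
#' same events, m); per-side stance and initial double-support durations as
#' \% of the stride containing each retained step; cadence (steps/min, from
#' the mean retained step duration); and walking speed (sacrum anterior
#' displacement over the span of the retained windows, m/s).
#'
#' @param events a `gait_events` object for the trial.
#' @param traj the (filtered) `marker_trajectory_set` of the same trial.
#' @param windows data.frame of retained step windows for this trial
#'   (subset of [select_steady_state()] output).
#' @param stabilize_s heel positions are sampled this long after each heel
#'   strike (default 0.04 s), once the zero-phase filter has settled on the
#'   foot-flat position; both feet are still in stance then (initial double
#'   support lasts longer than this at walking cadences).
#' @return list with `steps` (per-step data.frame: side, step length, width,
#'   duration, stance \%, double support \%) and trial-level `cadence`,
#'   `speed`.
#' @export
spatiotemporal <- function(events, traj, windows, stabilize_s = 0.04) {
  if (!nrow(windows)) stop("no retained step windows for this trial")
  axes <- detect_axes(traj)
  fs <- traj$sampling_rate
  lag <- round(stabilize_s * fs)
  sac_a <- axis_coord(traj, "sacrum", axes, "anterior")
  heel_a <- list(left = axis_coord(traj, "l_heel", axes, "anterior"),
                 right = axis_coord(traj, "r_heel", axes, "anterior"))
  heel_m <- list(left = axis_coord(traj, "l_heel", axes, "ml"),
                 right = axis_coord(traj, "r_heel", axes, "ml"))
  per_step <- lapply(seq_len(nrow(windows)), function(i) {
    side <- windows$side[i]; contra <- if (side == "left") "right" else "left"
    h0 <- windows$start_frame[i]; h1 <- windows$end_frame[i]
    n <- traj$n_frames
    s0 <- min(h0 + lag, n); s1 <- min(h1 + lag, n)
    step_len <- (heel_a[[side]][s1] - heel_a[[contra]][s0]) / 1000
    width <- abs(heel_m[[side]][s1] - heel_m[[contra]][s0]) / 1000
    dur <- (h1 - h0) / fs
    # stride of this side starting at h1 (fall back to the stride ending there)
    hs <- events[[side]]$heel_strike; tos <- events[[side]]$toe_off
    k <- match(h1, hs)
    stance <- ds <- NA_real_
    stride_start <- stride_end <- NA_integer_
    if (!is.na(k) && k < length(hs)) {
      stride_start <- hs[k]; stride_end <- hs[k + 1]
    } else if (!is.na(k) && k > 1) {
      stride_start <- hs[k - 1]; stride_end <- hs[k]
    }
    if (!is.na(stride_start)) {
      stride_t <- stride_end - stride_start
      to_in <- tos[tos > stride_start & tos < stride_end]
      if (length(to_in)) stance <- 100 * (to_in[1] - stride_start) / stride_t
      cto <- events[[contra]]$toe_off
      cto_in <- cto[cto > stride_start & cto < stride_end]
      if (length(cto_in)) ds <- 100 * (cto_in[1] - stride_start) / stride_t
    }
    data.frame(side = side, step_length_m = step_len, step_width_m = width,
               step_duration_s = dur, stance_pct = stance,
               double_support_pct = ds)
  })
  steps <- do.call(rbind, per_step)
  f0 <- min(windows$start_frame); f1 <- max(windows$end_frame)
  list(steps = steps,
       cadence = 60 / mean(steps$step_duration_s),
       speed = (sac_a[f1] - sac_a[f0]) / 1000 / ((f1 - f0) / fs))
}

#' Aggregate per-trial values into subject-session parameters
#'
#' Means over retained steps/trials for every variable, a row shaped like
#' one line of the study's parameter table. Spatial asymmetry is computed
#' from the per-side mean step lengths (primary definition); the mean of
#' per-step asymmetries is also reported. Side-dependent quantities are
#' mapped to affected (A) / unaffected (NA) columns through
#' `affected_side`; for control subjects (no affected side) the mapping is
#' dominant/non-dominant with `affected_side` naming the dominant side.
#'
#' @param trial_results list of per-trial results: each element a list with
#'   `st` (output of [spatiotemporal()]) and optionally `rom`, a named
#'   vector of RoMs (`hip_left`, `hip_right`, `knee_left`, ..., `trunk_sagittal`,
#'   `trunk_frontal`, `trunk_transverse`) for that trial.
#' @param subject_id,session identifiers carried into the output row.
#' @param affected_side `"left"` or `"right"`.
#' @return one-row data.frame of subject-session parameters
#'   (`cadence`, `speed_mps`, per-side `stance_pct_*`, `double_support_pct_*`,
#'   `step_length_m_*`, RoM columns, `step_width_m`,
#'   `spatial_asymmetry_pct`, `spatial_asymmetry_pct_per_step`, `n_steps_used`).
#' @export
aggregate_session <- function(trial_results, subject_id = "s", session = "baseline",
                              affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  if (!length(trial_results)) stop("zero retained trials: subject-session excluded")
  steps <- do.call(rbind, lapply(trial_results, function(x) x$st$steps))
  side_mean <- function(col, side)
    mean(steps[[col]][steps$side == side], na.rm = TRUE)
  a_side <- affected_side
  na_side <- if (a_side == "left") "right" else "left"
  sl_a <- side_mean("step_length_m", a_side)
  sl_na <- side_mean("step_length_m", na_side)
  per_step_asym <- {
    la <- steps$step_length_m[steps$side == a_side]
    lb <- steps$step_length_m[steps$side == na_side]
    npair <- min(length(la), length(lb))
    mean(spatial_asymmetry(la[seq_len(npair)], lb[seq_len(npair)]))
  }
  roms <- lapply(trial_results, function(x) x$rom)
  rom_mean <- function(key) {
    v <- vapply(roms, function(r) if (is.null(r)) NA_real_ else r[[key]],
                numeric(1))
    mean(v, na.rm = TRUE)
  }
  out <- data.frame(
    subject_id = subject_id, session = session, affected_side = a_side,
    cadence = mean(vapply(trial_results, function(x) x$st$cadence, numeric(1))),
    speed_mps = mean(vapply(trial_results, function(x) x$st$speed, numeric(1))),
    stance_pct_a = side_mean("stance_pct", a_side),
    stance_pct_na = side_mean("stance_pct", na_side),
    double_support_pct_a = side_mean("double_support_pct", a_side),
    double_support_pct_na = side_mean("double_support_pct", na_side),
    step_length_m_a = sl_a, step_length_m_na = sl_na,
    step_width_m = mean(steps$step_width_m),
    spatial_asymmetry_pct = spatial_asymmetry(sl_a, sl_na),
    spatial_asymmetry_pct_per_step = per_step_asym,
    hip_rom_a = rom_mean(paste0("hip_", a_side)),
    hip_rom_na = rom_mean(paste0("hip_", na_side)),
    knee_rom_a = rom_mean(paste0("knee_", a_side)),
    knee_rom_na = rom_mean(paste0("knee_", na_side)),
    ankle_rom_a = rom_mean(paste0("ankle_", a_side)),
    ankle_rom_na = rom_mean(paste0("ankle_", na_side)),
    trunk_rom_sagittal = rom_mean("trunk_sagittal"),
    trunk_rom_frontal = rom_mean("trunk_frontal"),
    trunk_rom_transverse = rom_mean("trunk_transverse"),
    n_steps_used = nrow(steps),
    stringsAsFactors = FALSE)
  out
}
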