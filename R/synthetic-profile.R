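#' Construct a gait profile
#'
#' A `gait_profile` holds the ground-truth walking pattern of one subject at
#' one session: step lengths of the affected/most-affected (A) and
#' unaffected/least-affected (NA) sides, cadence, per-side stance and initial
#' double-support percentages, step width, sagittal lower-limb ranges of
#' motion (RoM) and trunk RoMs in three planes. Walking speed is bound to the
#' identity `speed = mean step length x cadence / 60` and is derived when not
#' supplied; a supplied speed inconsistent with the identity (tolerance 1e-9)
#' is rejected.
#'
#' @param step_length_a,step_length_na step lengths (m) of the affected and
#'   unaffected sides.
#' @param cadence steps per minute.
#' @param stance_pct stance duration as \% of stride, per side; may be a
#'   single value or `c(A, NA)`; must lie in (50, 75).
#' @param step_width mediolateral distance between heel positions (m).
#' @param hip_rom,knee_rom,ankle_rom sagittal RoMs (degrees), single value or
#'   `c(A, NA)`.
#' @param trunk_rom trunk RoM (degrees), `c(sagittal, frontal, transverse)`.
#' @param double_support_pct per-side initial double support as \% of stride;
#'   defaults to `stance_pct - 50`, the value implied by symmetric
#'   left/right phasing.
#' @param speed optional walking speed (m/s); derived if `NULL`.
#' @return An object of class `gait_profile`.
#' @examples
#' p <- gait_profile(0.5, 0.5, cadence = 100, stance_pct = 62,
#'                   step_width = 0.16, hip_rom = 33, knee_rom = 48,
#'                   ankle_rom = 24, trunk_rom = c(3.5, 4, 7))
#' p$speed  # 0.5 * 100 / 60
#' @export
gait_profile <- function(step_length_a, step_length_na, cadence,
                         stance_pct = 62, step_width = 0.16,
                         hip_rom = 33, knee_rom = 48, ankle_rom = 24,
                         trunk_rom = c(3.5, 4.0, 7.0),
                         double_support_pct = NULL, speed = NULL) {
  two <- function(x) if (length(x) == 1) c(x, x) else x[1:2]
  stance_pct <- two(stance_pct)
  hip_rom <- two(hip_rom); knee_rom <- two(knee_rom); ankle_rom <- two(ankle_rom)
  if (length(trunk_rom) != 3) stop("trunk_rom must be c(sagittal, frontal, transverse)")
  vals <- c(step_length_a, step_length_na, cadence, step_width,
            hip_rom, knee_rom, ankle_rom, trunk_rom)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all step lengths, cadence, step width and RoMs must be finite and positive")
  if (any(stance_pct <= 50) || any(stance_pct >= 75))
    stop("stance_pct must lie in (50, 75)")
  if (is.null(double_support_pct)) double_support_pct <- stance_pct - 50
  double_support_pct <- two(double_support_pct)
  mean_step <- (step_length_a + step_length_na) / 2
  implied <- mean_step * cadence / 60
  if (is.null(speed)) {
    speed <- implied
  } else if (abs(speed - implied) > 1e-9) {
    stop("inconsistent profile: speed (", speed,
         ") != mean step length x cadence / 60 (", implied, ")")
  }
  structure(
    list(step_length_a = step_length_a, step_length_na = step_length_na,
         cadence = cadence, stance_pct = stance_pct,
         double_support_pct = double_support_pct, step_width = step_width,
         hip_rom = hip_rom, knee_rom = knee_rom, ankle_rom = ankle_rom,
         trunk_rom = trunk_rom, speed = speed),
    class = "gait_profile"
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>",
      sprintf("steps A/NA %.3f/%.3f m, cadence %.1f steps/min, speed %.3f m/s\n",
              x$step_length_a, x$step_length_na, x$cadence, x$speed))
  cat(sprintf("  stance %.1f/%.1f%%, width %.3f m, RoM hip %.1f/%.1f knee %.1f/%.1f ankle %.1f/%.1f, trunk %s deg\n",
              x$stance_pct[1], x$stance_pct[2], x$step_width,
              x$hip_rom[1], x$hip_rom[2], x$knee_rom[1], x$knee_rom[2],
              x$ankle_rom[1], x$ankle_rom[2],
              paste(round(x$trunk_rom, 1), collapse = "/")))
  invisible(x)
}

# Two-harmonic periodic template scaled to a target range of motion.
# phase in radians; shape constants give a single maximum and minimum per
# cycle for the a2 values used below (|a2| <= 0.45).
harmonic_curve <- function(t, period, rom, mean = 0, phase = 0,
                           a2 = 0.2, p2 = 0.6) {
  w <- 2 * pi / period
  raw <- function(x) cos(x) + a2 * cos(2 * x + p2)
  grid <- raw(seq(0, 2 * pi, length.out = 2048))
  scale <- rom / (max(grid) - min(grid))
  mean + scale * (raw(w * t + phase) - (max(grid) + min(grid)) / 2)
}
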