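#' Marker dictionary and body-model constants
#'
#' The package uses a reduced 13-marker set sufficient to derive every
#' reported gait variable: sacrum, left/right anterior superior iliac spines
#' (ASIS), lateral knees, lateral malleoli, heels, toes, acromia and C7.
#' Geometric constants (segment lengths, joint-centre offsets from the sacrum
#' in the pelvis frame) are shared between the forward simulator and the
#' angle-reconstruction routines, playing the role the anthropometric scaling
#' tables play in laboratory gait models.
#'
#' Offsets are in millimetres, expressed in the pelvis frame
#' (x right, y anterior, z up); `side_sign` is +1 for right, -1 for left.
#'
#' @return A named list of model constants.
#' @export
gait_marker_model <- function() {
  list(
    markers = c("sacrum", "l_asis", "r_asis", "l_knee", "r_knee",
                "l_malleolus", "r_malleolus", "l_heel", "r_heel",
                "l_toe", "r_toe", "l_acromion", "r_acromion", "c7"),
    pelvis_height = 1000,           # sacrum height (mm)
    hip_offset    = c(90, 50, -80), # |x|, y, z from sacrum, pelvis frame
    asis_offset   = c(120, 180, -30),
    thigh_length  = 410,
    shank_length  = 400,
    foot_length   = 150,            # heel -> toe marker distance
    heel_height   = 30,             # heel marker height in stance (mm)
    trunk_length  = 500,            # sacrum -> C7
    acromion_offset = c(180, 0, -20), # from C7, trunk frame
    swing_lift    = 60              # heel lift at mid swing (mm)
  )
}

#' Construct a marker trajectory set
#'
#' Container for one walking trial: labelled 3D marker positions over frames
#' at a fixed sampling rate. Positions are in millimetres. All markers must
#' share the same number of frames; up to 10\% of frames per marker may be
#' missing (NA) before interpolation.
#'
#' @param trial_id character trial identifier.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param markers named list of n_frames x 3 numeric matrices (mm).
#' @return An object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(trial_id, sampling_rate, markers) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!length(markers) || is.null(names(markers)))
    stop("markers must be a named list of n x 3 matrices")
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1)
    stop("all markers must share the same number of frames")
  for (m in names(markers)) {
    mat <- markers[[m]]
    if (!is.matrix(mat) || ncol(mat) != 3)
      stop("marker '", m, "' is not an n x 3 matrix")
    frac_na <- mean(!complete.cases(mat))
    if (frac_na > 0.10)
      stop("marker '", m, "' has ", round(100 * frac_na, 1),
           "% missing frames (> 10% allowed)")
  }
  structure(
    list(trial_id = trial_id, sampling_rate = sampling_rate,
         markers = markers, n_frames = unname(nf[1])),
    class = "marker_trajectory_set"
  )
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat("<marker_trajectory_set> trial", x$trial_id, "\n")
  cat("  ", x$n_frames, "frames @", x$sampling_rate, "Hz,",
      length(x$markers), "markers:",
      paste(head(names(x$markers), 6), collapse = ", "),
      if (length(x$markers) > 6) "..." else "", "\n")
  invisible(x)
}

# Detect the laboratory axes from the sacrum path: anterior = axis of largest
# sacrum excursion (sign from net displacement), vertical = remaining axis
# with the largest mean absolute position, mediolateral = the third axis with
# sign completing a right-handed frame (ml = anterior x vertical).
#' Detect anterior/vertical/mediolateral axes of a trial
#'
#' @param traj a `marker_trajectory_set` containing a `sacrum` marker.
#' @return list with integer axis indices `anterior`, `vertical`, `ml` and
#'   signs `anterior_sign`, `ml_sign` (+1/-1); vertical is assumed +.
#' @export
detect_axes <- function(traj) {
  sac <- traj$markers$sacrum
  if (is.null(sac)) stop("sacrum marker required for axis detection")
  rng <- apply(sac, 2, function(v) diff(range(v, na.rm = TRUE)))
  ant <- which.max(rng)
  net <- sac[nrow(sac), ant] - sac[1, ant]
  ant_sign <- if (net >= 0) 1 else -1
  rest <- setdiff(1:3, ant)
  vert <- rest[which.max(abs(colMeans(sac[, rest, drop = FALSE],
                                      na.rm = TRUE)))]
  ml <- setdiff(rest, vert)
  # right-handed: e_ml = e_ant x e_vert
  ea <- ev <- numeric(3); ea[ant] <- ant_sign; ev[vert] <- 1
  cross <- c(ea[2] * ev[3] - ea[3] * ev[2],
             ea[3] * ev[1] - ea[1] * ev[3],
             ea[1] * ev[2] - ea[2] * ev[1])
  list(anterior = ant, vertical = vert, ml = ml,
       anterior_sign = ant_sign, ml_sign = unname(sign(cross[ml])))
}

# Return a marker's coordinate along a named lab axis, sign-corrected.
axis_coord <- function(traj, marker, axes, which = c("anterior", "vertical", "ml")) {
  which <- match.arg(which)
  m <- traj$markers[[marker]]
  if (is.null(m)) stop("marker '", marker, "' not present")
  switch(which,
         anterior = m[, axes$anterior] * axes$anterior_sign,
         vertical = m[, axes$vertical],
         ml       = m[, axes$ml] * axes$ml_sign)
}
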