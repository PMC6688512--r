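#' Joint and trunk angle series
#'
#' Reconstructs sagittal lower-limb joint angles and trunk angles from the
#' 13-marker model. Angles are relative segment angles in the plane of
#' interest (the first, flexion-extension axis of an ISB-style mediolateral-
#' first rotation sequence; only this angle is reported for the lower limbs,
#' which limits sensitivity to the remaining sequence choices):
#' \itemize{
#'   \item hip: thigh (hip centre to knee) versus the pelvis vertical;
#'     the hip centre is reconstructed from the sacrum and the ASIS-derived
#'     pelvis yaw using the shared body-model offsets of
#'     [gait_marker_model()].
#'   \item knee: flexion, thigh angle minus shank (knee to malleolus) angle.
#'   \item ankle: foot (heel to toe) pitch relative to the shank, as
#'     deviation from neutral.
#'   \item trunk: the sacrum-to-C7 axis versus vertical in the sagittal
#'     (flexion-extension) and frontal (bending) planes; the acromion line
#'     versus the laboratory mediolateral axis in the transverse plane
#'     (rotation).
#' }
#' Input markers should already be gap-free and low-pass filtered.
#'
#' @param traj a filtered `marker_trajectory_set`.
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`, `"trunk"`.
#' @param side `"left"`, `"right"`, or `"none"` (trunk).
#' @param plane `"sagittal"` (lower limb) or, for the trunk, also
#'   `"frontal"` / `"transverse"`.
#' @return An object of class `joint_angle_series`: list with `angle`
#'   (degrees, one value per frame), `joint`, `side`, `plane`.
#' @export
joint_angle_series <- function(traj, joint = c("hip", "knee", "ankle", "trunk"),
                               side = c("left", "right", "none"),
                               plane = c("sagittal", "frontal", "transverse")) {
  joint <- match.arg(joint); side <- match.arg(side); plane <- match.arg(plane)
  if (joint != "trunk" && plane != "sagittal")
    stop("only sagittal-plane angles are computed for lower-limb joints")
  if (joint != "trunk" && side == "none")
    stop("side must be 'left' or 'right' for lower-limb joints")
  axes <- detect_axes(traj)
  mdl <- gait_marker_model()
  r2d <- 180 / pi
  get3 <- function(marker) cbind(axis_coord(traj, marker, axes, "ml"),
                                 axis_coord(traj, marker, axes, "anterior"),
                                 axis_coord(traj, marker, axes, "vertical"))
  seg_check <- function(v, what) {
    if (any(sqrt(rowSums(v^2)) < 1e-6))
      stop("degenerate ", what, " segment (zero length)")
    v
  }
  if (joint == "trunk") {
    ang <- switch(plane,
      sagittal = {
        d <- seg_check(get3("c7") - get3("sacrum"), "trunk")
        atan2(d[, 2], d[, 3]) * r2d
      },
      frontal = {
        d <- seg_check(get3("c7") - get3("sacrum"), "trunk")
        atan2(d[, 1], d[, 3]) * r2d
      },
      transverse = {
        sv <- seg_check(get3("r_acromion") - get3("l_acromion"), "shoulder")
        atan2(sv[, 2], sv[, 1]) * r2d
      })
  } else {
    pre <- substr(side, 1, 1)
    ss <- if (side == "right") 1 else -1
    sac <- get3("sacrum")
    # pelvis yaw from the ASIS line, then hip centre from model offsets
    av <- seg_check(get3("r_asis") - get3("l_asis"), "pelvis")
    psi <- atan2(av[, 2], av[, 1])
    # anthropometric scaling: model offsets scale with the subject's
    # inter-ASIS distance, making angles invariant to body size
    s_pelvis <- mean(sqrt(rowSums(av^2))) / (2 * mdl$asis_offset[1])
    off <- mdl$hip_offset * s_pelvis
    hip_c <- cbind(sac[, 1] + ss * off[1] * cos(psi) - off[2] * sin(psi),
                   sac[, 2] + ss * off[1] * sin(psi) + off[2] * cos(psi),
                   sac[, 3] + off[3])
    thigh <- seg_check(get3(paste0(pre, "_knee")) - hip_c, "thigh")
    th_thigh <- atan2(thigh[, 2], -thigh[, 3]) * r2d
    if (joint == "hip") {
      ang <- th_thigh
    } else {
      shank <- seg_check(get3(paste0(pre, "_malleolus")) -
                           get3(paste0(pre, "_knee")), "shank")
      th_shank <- atan2(shank[, 2], -shank[, 3]) * r2d
      if (joint == "knee") {
        ang <- th_thigh - th_shank
      } else {
        foot <- seg_check(get3(paste0(pre, "_toe")) -
                            get3(paste0(pre, "_heel")), "foot")
        phi_foot <- atan2(foot[, 3], foot[, 2]) * r2d
        ang <- phi_foot - th_shank
      }
    }
  }
  if (any(!is.finite(ang))) stop("non-finite angles computed")
  structure(list(angle = as.numeric(ang), joint = joint, side = side,
                 plane = plane), class = "joint_angle_series")
}

#' Range of motion over retained step windows
#'
#' Maximum minus minimum of an angle series within the union of the supplied
#' step windows (or the whole trial when `windows` is `NULL`).
#'
#' @param series a `joint_angle_series` (or plain numeric vector).
#' @param windows optional data.frame with `start_frame`/`end_frame` columns
#'   as returned by [select_steady_state()].
#' @return RoM in degrees (>= 0).
#' @export
range_of_motion <- function(series, windows = NULL) {
  ang <- if (inherits(series, "joint_angle_series")) series$angle else series
  idx <- if (is.null(windows)) seq_along(ang) else {
    if (!nrow(windows)) stop("empty window set")
    sort(unique(unlist(mapply(seq, windows$start_frame, windows$end_frame,
                              SIMPLIFY = FALSE))))
  }
  if (!length(idx)) stop("empty window set")
  diff(range(ang[idx]))
}
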