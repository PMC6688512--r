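#' Detect gait events from marker trajectories
#'
#' Coordinate-based event detection: a heel strike is a local maximum of the
#' heel's anterior position relative to the sacrum; a toe-off is the minimum
#' of the toe's relative anterior position between two consecutive heel
#' strikes of the same side. The anterior axis (and walking direction) is
#' auto-detected from the sacrum path, so the detector is direction-agnostic.
#' Per-side alternation (HS, TO, HS, ...) holds by construction; the first
#' retained event on each side is a heel strike. A velocity-threshold
#' fallback (`method = "velocity"`) marks heel strike/toe-off where the
#' heel/toe anterior velocity falls below / rises above a fraction of the
#' sacrum velocity.
#'
#' @param traj a filtered `marker_trajectory_set` with heel, toe and sacrum
#'   markers (see [filter_markers()]).
#' @param min_prominence_frac minimum peak height as a fraction of the signal
#'   range, measured from mid-range (default 0.25).
#' @param method `"coordinate"` (default) or `"velocity"`.
#' @param velocity_frac velocity threshold as a fraction of mean sacrum
#'   speed, for the fallback method.
#' @return An object of class `gait_events`: per side, ordered heel-strike
#'   and toe-off frame indices.
#' @export
detect_gait_events <- function(traj, min_prominence_frac = 0.25,
                               method = c("coordinate", "velocity"),
                               velocity_frac = 0.5) {
  method <- match.arg(method)
  axes <- detect_axes(traj)
  sac <- axis_coord(traj, "sacrum", axes, "anterior")
  out <- list()
  for (side in c("left", "right")) {
    pre <- substr(side, 1, 1)
    heel <- axis_coord(traj, paste0(pre, "_heel"), axes, "anterior") - sac
    toe  <- axis_coord(traj, paste0(pre, "_toe"),  axes, "anterior") - sac
    if (method == "coordinate") {
      hs <- find_peaks(heel, min_prominence_frac)
    } else {
      fs <- traj$sampling_rate
      vsac <- mean(diff(sac)) * fs
      vheel <- c(0, diff(axis_coord(traj, paste0(pre, "_heel"), axes,
                                    "anterior"))) * fs
      slow <- vheel < velocity_frac * vsac
      starts <- which(diff(c(FALSE, slow)) == 1)
      hs <- starts[heel[starts] > stats::median(heel)]
    }
    if (length(hs) < 3)
      stop("fewer than 3 heel strikes detected on the ", side,
           " side: trial rejected")
    to <- integer(0)
    for (k in seq_len(length(hs) - 1)) {
      seg <- (hs[k] + 1):(hs[k + 1] - 1)
      to <- c(to, seg[which.min(toe[seg])])
    }
    out[[side]] <- list(heel_strike = hs, toe_off = to)
  }
  structure(c(out, list(sampling_rate = traj$sampling_rate,
                        n_frames = traj$n_frames)),
            class = "gait_events")
}

# local maxima above mid-range + prominence fraction, with greedy pruning of
# peaks closer than half the median inter-peak interval
find_peaks <- function(x, min_prominence_frac = 0.25) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  rng <- range(x)
  thr <- rng[1] + (0.5 + min_prominence_frac / 2) * diff(rng)
  cand <- cand[x[cand] >= thr]
  if (length(cand) > 2) {
    min_sep <- 0.5 * median(diff(cand))
    keep <- order(x[cand], decreasing = TRUE)
    sel <- integer(0)
    for (i in keep) if (!length(sel) || all(abs(cand[i] - cand[sel]) > min_sep))
      sel <- c(sel, i)
    cand <- sort(cand[sel])
  }
  cand
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>\n")
  for (s in c("left", "right"))
    cat(sprintf("  %-5s %d heel strikes, %d toe-offs\n",
                s, length(x[[s]]$heel_strike), length(x[[s]]$toe_off)))
  invisible(x)
}

#' Select steady-state step windows across a session's trials
#'
#' Applies the steady-state policy of a session: the first walking trial is
#' rejected and the subsequent `keep_trials` trials retained; within each
#' retained trial the first and last `trim_steps` steps of each side are
#' excluded (acceleration/deceleration), and the central `central_steps`
#' steps per side are kept. With 6 trials and the defaults this yields
#' 5 trials x 2 sides x 2 steps = 20 step windows per subject-session. When
#' the number of usable steps is odd the central pair is tied toward the
#' later pair. A step of one side is the half-open interval from the
#' preceding contralateral heel strike to that side's heel strike.
#'
#' @param events_list ordered list of `gait_events`, one per trial of a
#'   subject-session (>= `1 + keep_trials` required).
#' @param policy list with `drop_first_trials`, `keep_trials`, `trim_steps`,
#'   `central_steps`.
#' @return list with `windows`: a data.frame (trial, side, step_index,
#'   start_frame, end_frame, hs_frame) of retained step windows, and
#'   `exclusions`: character log of excluded trials.
#' @export
select_steady_state <- function(events_list,
                                policy = list(drop_first_trials = 1,
                                              keep_trials = 5,
                                              trim_steps = 2,
                                              central_steps = 2)) {
  need <- policy$drop_first_trials + policy$keep_trials
  if (length(events_list) < need)
    stop("need at least ", need, " trials per subject-session, got ",
         length(events_list))
  use <- events_list[(policy$drop_first_trials + 1):need]
  rows <- list(); excl <- character(0)
  for (ti in seq_along(use)) {
    ev <- use[[ti]]
    trial_rows <- list(); ok <- TRUE
    for (side in c("left", "right")) {
      contra <- if (side == "left") "right" else "left"
      hs <- ev[[side]]$heel_strike
      chs <- ev[[contra]]$heel_strike
      # steps of this side: HS with a preceding contralateral HS
      prev <- vapply(hs, function(h) {
        p <- chs[chs < h]
        if (length(p)) max(p) else NA_integer_
      }, numeric(1))
      steps <- which(!is.na(prev))
      ns <- length(steps)
      if (ns < 2 * policy$trim_steps + policy$central_steps) {
        excl <- c(excl, sprintf(
          "trial %d: only %d steps on %s side after trimming rule", ti, ns, side))
        ok <- FALSE
        break
      }
      usable <- steps[(policy$trim_steps + 1):(ns - policy$trim_steps)]
      nu <- length(usable)
      start <- ceiling(nu / 2)  # odd leftover ties toward the later pair
      start <- min(max(start, 1), nu - policy$central_steps + 1)
      cen <- usable[start:(start + policy$central_steps - 1)]
      trial_rows[[side]] <- data.frame(
        trial = ti + policy$drop_first_trials, side = side,
        step_index = match(cen, steps),
        start_frame = prev[cen], end_frame = hs[cen], hs_frame = hs[cen])
    }
    if (ok) rows <- c(rows, trial_rows)
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(0), side = character(0), step_index = integer(0),
               start_frame = integer(0), end_frame = integer(0),
               hs_frame = integer(0))
  rownames(windows) <- NULL
  list(windows = windows, exclusions = excl)
}
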