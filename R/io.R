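#' Read marker trajectories from long-format CSV
#'
#' Accepts the package's long format: columns `trial`, `frame`, `marker`,
#' `x`, `y`, `z` (plus optional `sampling_rate`). Marker labels are
#' lower-cased and matched against the 13-marker dictionary of
#' [gait_marker_model()]; unknown labels are skipped with a warning. Units
#' are auto-detected (metres vs millimetres) from the coordinate magnitudes
#' and converted to millimetres internally; files whose magnitudes are
#' ambiguous are rejected.
#'
#' @param path CSV file path.
#' @param sampling_rate sampling frequency in Hz; required unless the file
#'   carries a `sampling_rate` column.
#' @return a `marker_trajectory_set` (single trial) or a named list of them
#'   (several trials in one file).
#' @export
read_markers <- function(path, sampling_rate = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "frame", "marker", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("malformed marker CSV: need columns ", paste(need, collapse = ", "))
  if (is.null(sampling_rate)) {
    if (!"sampling_rate" %in% names(d))
      stop("sampling_rate must be given or present as a column")
    sampling_rate <- d$sampling_rate[1]
  }
  d$marker <- tolower(d$marker)
  known <- gait_marker_model()$markers
  unknown <- setdiff(unique(d$marker), known)
  if (length(unknown)) {
    warning("skipping unknown marker labels: ", paste(unknown, collapse = ", "))
    d <- d[d$marker %in% known, ]
  }
  if (!nrow(d)) stop("no known markers in file")
  mx <- max(abs(c(d$x, d$y, d$z)), na.rm = TRUE)
  scale <- if (mx < 20) 1000 else if (mx > 200) 1 else
    stop("ambiguous coordinate units (max |value| = ", signif(mx, 3),
         "): neither metres nor millimetres")
  out <- lapply(split(d, d$trial), function(dt) {
    dt <- dt[order(dt$marker, dt$frame), ]
    nf <- max(dt$frame)
    mk <- lapply(split(dt, dt$marker), function(dm) {
      m <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
      m[dm$frame, ] <- as.matrix(dm[, c("x", "y", "z")]) * scale
      m
    })
    marker_trajectory_set(dt$trial[1], sampling_rate, mk)
  })
  if (length(out) == 1) out[[1]] else out
}

#' Write marker trajectories to long-format CSV
#'
#' Inverse of [read_markers()]; positions are written in millimetres, and a
#' `sampling_rate` column is included so the file is self-describing.
#'
#' @param traj a `marker_trajectory_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(traj, path) {
  rows <- lapply(names(traj$markers), function(nm) {
    m <- traj$markers[[nm]]
    data.frame(trial = traj$trial_id, frame = seq_len(nrow(m)), marker = nm,
               x = m[, 1], y = m[, 2], z = m[, 3],
               sampling_rate = traj$sampling_rate)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write detected gait events to CSV
#'
#' One row per event: `trial`, `side`, `event_type` (`heel_strike` /
#' `toe_off`), `frame` (1-based) and `time_s`.
#'
#' @param events a `gait_events` object.
#' @param path output file path.
#' @param trial_id trial identifier written in the `trial` column.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, trial_id = "trial") {
  rows <- list()
  for (side in c("left", "right")) for (tp in c("heel_strike", "toe_off")) {
    fr <- events[[side]][[tp]]
    if (length(fr))
      rows[[length(rows) + 1]] <- data.frame(
        trial = trial_id, side = side, event_type = tp, frame = fr,
        time_s = (fr - 1) / events$sampling_rate)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Validated configuration for [run_pipeline()]. All thresholds of the
#' analysis are surfaced here: the low-pass cut-off, the speed-matching
#' toggle, the normalization band width `normalization_k`, the
#' backward-elimination `removal_alpha`, and the cohort-generation knobs.
#'
#' @param seed integer seed driving all randomness.
#' @param out_dir output directory for the report bundle.
#' @param level `"markers"` (full marker-level simulation and extraction)
#'   or `"parameters"` (parameter-level simulation; fast).
#' @param n_patients,n_controls,n_trials_per_session cohort sizes.
#' @param n_strides strides per simulated trial (marker level).
#' @param sampling_rate Hz; `cutoff_hz` low-pass cut-off; `filter_order`
#'   effective Butterworth order.
#' @param noise_sd_marker marker noise SD, mm.
#' @param speed_matching logical: restrict control trials to the patient
#'   speed band.
#' @param normalization_k normalization band width in control SDs.
#' @param removal_alpha backward-elimination removal threshold.
#' @param predictors candidate predictors offered to every delta model
#'   (the outcome's baseline value is always added and protected).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1, out_dir = tempfile("pdgait_run_"),
                            level = c("parameters", "markers"),
                            n_patients = 12, n_controls = 8,
                            n_trials_per_session = 6, n_strides = 8,
                            sampling_rate = 300, cutoff_hz = 6,
                            filter_order = 4, noise_sd_marker = 1,
                            speed_matching = TRUE, normalization_k = 1,
                            removal_alpha = 0.10,
                            predictors = c("age", "sex_f", "disease_duration",
                                           "updrs2", "updrs3", "hy_stage", "led")) {
  level <- match.arg(level)
  if (normalization_k < 0) stop("normalization_k must be >= 0")
  if (removal_alpha <= 0 || removal_alpha > 1)
    stop("removal_alpha must be in (0, 1]")
  structure(list(seed = seed, out_dir = out_dir, level = level,
                 n_patients = n_patients, n_controls = n_controls,
                 n_trials_per_session = n_trials_per_session,
                 n_strides = n_strides, sampling_rate = sampling_rate,
                 cutoff_hz = cutoff_hz, filter_order = filter_order,
                 noise_sd_marker = noise_sd_marker,
                 speed_matching = speed_matching,
                 normalization_k = normalization_k,
                 removal_alpha = removal_alpha, predictors = predictors),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_analysis_config()]: an `analysis_config`;
#'   [write_analysis_config()]: `path`, invisibly.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' @rdname read_analysis_config
#' @param config an `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
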