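#' Extract gait parameters from one session's walking trials
#'
#' The measurement chain applied to each subject-session: gap interpolation,
#' zero-lag low-pass filtering, gait event detection, steady-state step
#' selection across trials, spatio-temporal parameters and joint/trunk RoMs
#' over the retained windows.
#'
#' @param trajs ordered list of raw `marker_trajectory_set` trials
#'   (>= 6; the first is discarded by the steady-state policy).
#' @param cutoff_hz,filter_order low-pass settings (see [zero_lag_lowpass()]).
#' @param policy steady-state policy (see [select_steady_state()]).
#' @return list with `per_trial` (per retained trial: `st` from
#'   [spatiotemporal()], `rom` named RoM vector, `trial` index), and
#'   `exclusions` (character log).
#' @export
extract_session <- function(trajs, cutoff_hz = 6, filter_order = 4,
                            policy = list(drop_first_trials = 1,
                                          keep_trials = 5, trim_steps = 2,
                                          central_steps = 2)) {
  prepared <- lapply(trajs, function(tr) {
    trf <- filter_markers(interpolate_gaps(tr), cutoff = cutoff_hz,
                          order = filter_order)
    list(trf = trf, ev = detect_gait_events(trf))
  })
  sel <- select_steady_state(lapply(prepared, `[[`, "ev"), policy)
  per_trial <- list()
  for (ti in unique(sel$windows$trial)) {
    win <- sel$windows[sel$windows$trial == ti, ]
    p <- prepared[[ti]]
    st <- spatiotemporal(p$ev, p$trf, win)
    rom <- c(
      hip_left = range_of_motion(joint_angle_series(p$trf, "hip", "left"), win),
      hip_right = range_of_motion(joint_angle_series(p$trf, "hip", "right"), win),
      knee_left = range_of_motion(joint_angle_series(p$trf, "knee", "left"), win),
      knee_right = range_of_motion(joint_angle_series(p$trf, "knee", "right"), win),
      ankle_left = range_of_motion(joint_angle_series(p$trf, "ankle", "left"), win),
      ankle_right = range_of_motion(joint_angle_series(p$trf, "ankle", "right"), win),
      trunk_sagittal = range_of_motion(
        joint_angle_series(p$trf, "trunk", "none", "sagittal"), win),
      trunk_frontal = range_of_motion(
        joint_angle_series(p$trf, "trunk", "none", "frontal"), win),
      trunk_transverse = range_of_motion(
        joint_angle_series(p$trf, "trunk", "none", "transverse"), win))
    per_trial[[length(per_trial) + 1]] <- list(st = st, rom = rom, trial = ti)
  }
  list(per_trial = per_trial, exclusions = sel$exclusions)
}

# session truth/extraction -> tidy one-row parameter set (parameter level)
session_row_from_truth <- function(s) {
  data.frame(
    subject_id = s$subject_id, session = s$session,
    cadence = s$cadence, speed_mps = s$speed,
    stance_pct_a = s$stance_a, stance_pct_na = s$stance_na,
    double_support_pct_a = s$stance_na - 50,
    double_support_pct_na = s$stance_a - 50,
    step_length_m_a = s$step_length_a, step_length_m_na = s$step_length_na,
    step_width_m = s$step_width,
    spatial_asymmetry_pct = s$asymmetry,
    hip_rom_a = s$hip_rom_a, hip_rom_na = s$hip_rom_na,
    knee_rom_a = s$knee_rom_a, knee_rom_na = s$knee_rom_na,
    ankle_rom_a = s$ankle_rom_a, ankle_rom_na = s$ankle_rom_na,
    trunk_rom_sagittal = s$trunk_sagittal,
    trunk_rom_frontal = s$trunk_frontal,
    trunk_rom_transverse = s$trunk_transverse,
    n_steps_used = NA_integer_, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, kinematics/extraction, parameter
#' aggregation, speed matching, group statistics, delta computation,
#' anchor-based responsiveness (MCID), and clinical prediction — and writes
#' a report bundle to `config$out_dir`: `parameters.csv`,
#' `comparisons.csv`, `deltas.csv`, `mcid.json`, `regression.json`,
#' `run.log`. Every exclusion (rejected trial, unmatched control) is logged
#' with its reason. The run is deterministic for a fixed config and seed.
#'
#' At `level = "markers"` each trial is simulated at marker level and the
#' parameters are re-extracted through the full measurement chain; at
#' `level = "parameters"` the per-trial parameter realizations are analysed
#' directly (fast path with identical downstream statistics).
#'
#' @param config an [analysis_config()].
#' @return list with the parameter table, comparison table, delta table,
#'   MCID results, regression models and the output directory, invisibly
#'   mirror-written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  stage <- "simulate"
  result <- tryCatch({
    cc <- cohort_config(n_patients = config$n_patients,
                        n_controls = config$n_controls,
                        n_trials_per_session = config$n_trials_per_session,
                        sampling_rate = config$sampling_rate,
                        noise_sd_marker = config$noise_sd_marker,
                        seed = config$seed)
    cohort <- generate_cohort(cc)
    say("simulate: ", nrow(cohort$clinical), " subjects, ",
        nrow(cohort$trials), " trials")

    stage <- "kinematics"
    keys <- unique(cohort$trials[, c("subject_id", "session")])
    per_session <- vector("list", nrow(keys))
    trial_speed_rows <- list()
    for (i in seq_len(nrow(keys))) {
      sid <- keys$subject_id[i]; ses <- keys$session[i]
      aff <- cohort$clinical$affected_side[cohort$clinical$subject_id == sid]
      tr <- cohort$trials[cohort$trials$subject_id == sid &
                            cohort$trials$session == ses, ]
      if (config$level == "markers") {
        trajs <- lapply(seq_len(nrow(tr)), function(j) {
          prof <- cohort_trial_profile(cohort, sid, ses, tr$trial[j])
          generate_trial(prof, n_strides = config$n_strides,
                         sampling_rate = config$sampling_rate,
                         noise_sd = config$noise_sd_marker,
                         affected_side = aff,
                         trial_id = paste(sid, ses, tr$trial[j], sep = "_"))$traj
        })
        ex <- extract_session(trajs, cutoff_hz = config$cutoff_hz,
                              filter_order = config$filter_order)
        for (e in ex$exclusions) say(sid, "/", ses, " ", e)
        per_trial <- ex$per_trial
        speeds <- vapply(per_trial, function(x) x$st$speed, numeric(1))
        trials_idx <- vapply(per_trial, `[[`, numeric(1), "trial")
      } else {
        # parameter level: analysed trials are 2..n (first rejected)
        use <- tr[-1, ]
        per_trial <- lapply(seq_len(nrow(use)), function(j) {
          row <- use[j, ]
          sides <- if (aff == "left") c("left", "right") else c("right", "left")
          steps <- data.frame(
            side = rep(sides, each = 2),
            step_length_m = rep(c(row$step_length_a, row$step_length_na), each = 2),
            step_width_m = row$step_width,
            step_duration_s = 60 / row$cadence,
            stance_pct = rep(c(row$stance_a, row$stance_na), each = 2),
            double_support_pct = rep(c(row$stance_na, row$stance_a) - 50,
                                     each = 2))
          rom <- setNames(
            as.numeric(row[c(
              if (aff == "left") c("hip_rom_a", "hip_rom_na") else c("hip_rom_na", "hip_rom_a"),
              if (aff == "left") c("knee_rom_a", "knee_rom_na") else c("knee_rom_na", "knee_rom_a"),
              if (aff == "left") c("ankle_rom_a", "ankle_rom_na") else c("ankle_rom_na", "ankle_rom_a"),
              "trunk_sagittal", "trunk_frontal", "trunk_transverse")]),
            c("hip_left", "hip_right", "knee_left", "knee_right",
              "ankle_left", "ankle_right", "trunk_sagittal", "trunk_frontal",
              "trunk_transverse"))
          list(st = list(steps = steps, cadence = row$cadence,
                         speed = row$speed), rom = rom, trial = row$trial)
        })
        speeds <- use$speed
        trials_idx <- use$trial
      }
      per_session[[i]] <- list(subject_id = sid, session = ses,
                               affected_side = aff, per_trial = per_trial,
                               speeds = speeds, trials_idx = trials_idx,
                               group = tr$group[1])
      for (k in seq_along(speeds))
        trial_speed_rows[[length(trial_speed_rows) + 1]] <- data.frame(
          subject_id = sid, session = ses, trial = trials_idx[k],
          group = tr$group[1], speed = speeds[k])
    }
    trial_speeds <- do.call(rbind, trial_speed_rows)

    stage <- "parameters"
    aggregate_one <- function(ps, keep = NULL) {
      pt <- ps$per_trial
      if (!is.null(keep)) pt <- pt[keep]
      if (!length(pt)) return(NULL)
      cbind(aggregate_session(pt, subject_id = ps$subject_id,
                              session = ps$session,
                              affected_side = ps$affected_side),
            group = ps$group)
    }
    parameters <- do.call(rbind, Filter(Negate(is.null),
                                        lapply(per_session, aggregate_one)))

    stage <- "matching"
    if (config$speed_matching) {
      for (ses in c("baseline", "followup")) {
        pat <- parameters[parameters$group == "patient" &
                            parameters$session == ses, "speed_mps"]
        mu <- mean(pat); sdv <- sd(pat)
        say("matching/", ses, ": patient speed ", round(mu, 3), " +/- ",
            round(sdv, 3), " m/s")
        for (i in seq_along(per_session)) {
          ps <- per_session[[i]]
          if (ps$group != "control" || ps$session != ses) next
          keep <- which(match_speed_trials(ps$speeds, mu, sdv))
          if (!length(keep)) {
            say("matching/", ses, ": control ", ps$subject_id,
                " excluded (no trial within the patient speed band)")
            parameters <- parameters[!(parameters$subject_id == ps$subject_id &
                                         parameters$session == ses), ]
          } else if (length(keep) < length(ps$speeds)) {
            say("matching/", ses, ": control ", ps$subject_id, " kept ",
                length(keep), "/", length(ps$speeds), " trials")
            new_row <- aggregate_one(ps, keep)
            sel <- parameters$subject_id == ps$subject_id &
              parameters$session == ses
            parameters[sel, names(new_row)] <- new_row
          }
        }
      }
    }

    stage <- "stats"
    numeric_vars <- setdiff(names(parameters),
                            c("subject_id", "session", "affected_side",
                              "group", "n_steps_used",
                              "spatial_asymmetry_pct_per_step"))
    comparisons <- do.call(rbind, lapply(c("baseline", "followup"), function(ses) {
      do.call(rbind, lapply(numeric_vars, function(v) {
        pa <- parameters[parameters$group == "patient" &
                           parameters$session == ses, v]
        co <- parameters[parameters$group == "control" &
                           parameters$session == ses, v]
        cr <- compare_groups(pa, co)
        data.frame(session = ses, variable = v,
                   mean_patient = mean(pa), sd_patient = sd(pa),
                   mean_control = mean(co), sd_control = sd(co),
                   test = cr$test, statistic = cr$statistic,
                   p_value = cr$p_value, cohen_d = cr$cohen_d,
                   n_patients = cr$n1, n_controls = cr$n2)
      }))
    }))

    stage <- "deltas"
    pat_ids <- unique(parameters$subject_id[parameters$group == "patient"])
    deltas <- do.call(rbind, lapply(pat_ids, function(sid) {
      b <- parameters[parameters$subject_id == sid &
                        parameters$session == "baseline", ]
      f <- parameters[parameters$subject_id == sid &
                        parameters$session == "followup", ]
      if (!nrow(b) || !nrow(f)) return(NULL)
      do.call(rbind, lapply(numeric_vars, function(v) data.frame(
        subject_id = sid, variable = v, value_baseline = b[[v]],
        value_10week = f[[v]], delta_pct = delta_pct(b[[v]], f[[v]]))))
    }))

    stage <- "responsiveness"
    ctrl_bl <- parameters[parameters$group == "control" &
                            parameters$session == "baseline", ]
    mcid <- list()
    for (spec in list(
      list(var = "spatial_asymmetry_pct", direction = "lower"),
      list(var = "trunk_rom_transverse", direction = "higher"))) {
      dv <- deltas[deltas$variable == spec$var, ]
      lab <- anchor_classify(dv$value_baseline, dv$value_10week,
                             mean(ctrl_bl[[spec$var]]),
                             sd(ctrl_bl[[spec$var]]),
                             direction = spec$direction,
                             k = config$normalization_k)
      score <- if (spec$direction == "lower") -dv$delta_pct else dv$delta_pct
      mcid[[spec$var]] <- tryCatch(
        unclass(mcid_analysis(score, lab, variable = spec$var)),
        error = function(e) {
          say("responsiveness: ", spec$var, " skipped (", conditionMessage(e), ")")
          NULL
        })
    }

    stage <- "prediction"
    clin <- cohort$clinical[cohort$clinical$group == "patient",
                            c("subject_id", config$predictors)]
    models <- list()
    for (ov in c("speed_mps", "cadence", "step_length_m_a",
                 "step_length_m_na", "trunk_rom_transverse")) {
      dv <- deltas[deltas$variable == ov, ]
      dd <- merge(clin, dv[, c("subject_id", "value_baseline", "delta_pct")],
                  by = "subject_id")
      names(dd)[names(dd) == "value_baseline"] <- "baseline"
      names(dd)[names(dd) == "delta_pct"] <- "outcome"
      models[[ov]] <- tryCatch({
        fit <- backward_eliminate(dd, "outcome",
                                  c(config$predictors, "baseline"),
                                  baseline = "baseline",
                                  removal_alpha = config$removal_alpha)
        c(fit[c("coefficients", "adjusted_r2", "f_stat", "model_p",
                "n", "dropped")], outcome = ov)
      }, error = function(e) {
        say("prediction: ", ov, " skipped (", conditionMessage(e), ")")
        NULL
      })
    }

    list(parameters = parameters, comparisons = comparisons, deltas = deltas,
         mcid = mcid, models = models)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  write.csv(result$parameters, file.path(config$out_dir, "parameters.csv"),
            row.names = FALSE)
  write.csv(result$comparisons, file.path(config$out_dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(result$deltas, file.path(config$out_dir, "deltas.csv"),
            row.names = FALSE)
  jsonlite::write_json(result$mcid, file.path(config$out_dir, "mcid.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(result$models,
                       file.path(config$out_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(c(result, list(out_dir = config$out_dir, log = log_lines)))
}
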