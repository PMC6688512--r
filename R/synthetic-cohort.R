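#' Default group-level gait parameter moments
#'
#' Mean/SD of each gait variable per group (patient/control) and session
#' (baseline/followup) used by [generate_cohort()]. The defaults reproduce
#' the study conditions of a 36-patient / 22-control speed-matched
#' rehabilitation cohort: higher cadence, shorter steps, reduced joint and
#' trunk-rotation RoMs and higher spatial asymmetry in patients at baseline.
#' Side-dependent RoMs carry separate affected (A) / unaffected (NA)
#' moments. Step lengths are parameterized as the subject's mean step length
#' plus the spatial asymmetry index (the two sides are derived from these),
#' and walking speed is derived from the profile identity
#' `speed = mean step x cadence / 60`, so the emergent speed distribution
#' sits slightly below a table that reports speed measured independently.
#'
#' @return nested list `param -> group -> session -> c(mean, sd)`.
#' @export
default_param_moments <- function() {
  m <- function(pb, pf, cb, cf)
    list(patient = list(baseline = pb, followup = pf),
         control = list(baseline = cb, followup = cf))
  list(
    cadence     = m(c(102.307, 16.146), c(107.143, 15.437),
                    c(88.280, 12.406),  c(95.573, 11.433)),
    mean_step   = m(c(0.412, 0.120), c(0.453, 0.112),
                    c(0.490, 0.058), c(0.522, 0.059)),
    asymmetry   = m(c(12.526, 11.824), c(7.229, 6.518),
                    c(6.764, 5.723),   c(5.496, 4.719)),
    stance      = m(c(63.445, 3.8), c(62.46, 3.8),
                    c(63.73, 2.1),  c(62.52, 1.8)),
    step_width  = m(c(0.164, 0.019), c(0.168, 0.021),
                    c(0.156, 0.024), c(0.159, 0.023)),
    hip_rom_a   = m(c(32.988, 8.449), c(36.001, 8.792),
                    c(38.975, 3.726), c(40.774, 4.120)),
    hip_rom_na  = m(c(33.039, 9.131), c(35.901, 8.911),
                    c(39.923, 3.953), c(42.414, 5.043)),
    knee_rom_a  = m(c(45.202, 2.074), c(45.439, 2.647),
                    c(52.355, 1.597), c(54.686, 1.443)),
    knee_rom_na = m(c(48.567, 1.915), c(49.876, 2.722),
                    c(54.075, 1.171), c(56.963, 1.061)),
    ankle_rom_a = m(c(23.730, 1.279), c(23.992, 0.948),
                    c(26.849, 1.772), c(26.977, 1.169)),
    ankle_rom_na= m(c(24.267, 1.064), c(25.408, 0.901),
                    c(26.833, 1.350), c(29.157, 1.269)),
    trunk_sagittal  = m(c(3.362, 1.365), c(3.948, 2.597),
                        c(3.468, 0.945), c(4.062, 1.848)),
    trunk_frontal   = m(c(4.008, 1.857), c(4.321, 2.355),
                        c(4.037, 1.589), c(4.671, 2.532)),
    trunk_transverse= m(c(6.996, 3.169), c(10.033, 5.822),
                        c(10.241, 3.758), c(12.098, 4.586))
  )
}

#' Default clinical-to-delta regression structure
#'
#' Ground-truth linear models linking baseline clinical covariates to the
#' change (follow-up minus baseline, native units) of the predictable gait
#' outcomes. Coefficient sets follow the clinical prediction table of the
#' emulated study; `sex_f` is the female indicator ([SEX_CODING]), and
#' `baseline` stands for the outcome's own baseline value. Residual SDs are
#' chosen to give adjusted R-squared in the 0.35-0.6 range observed for
#' such models. The speed entry is informational: in a generated cohort
#' speed is derived from cadence and step length, so its change is emergent
#' rather than directly imposed.
#'
#' @return named list per outcome: `predictors`, `coefs`
#'   (intercept first), `sigma`, `applied`.
#' @export
default_regression_truth <- function() {
  list(
    speed = list(predictors = c("updrs3", "sex_f", "baseline"),
                 coefs = c(1.264, -0.018, -0.248, -0.446),
                 sigma = 0.15, applied = FALSE),
    cadence = list(predictors = c("updrs2", "sex_f", "baseline"),
                   coefs = c(69.212, -0.523, -8.518, -0.402),
                   sigma = 9, applied = TRUE),
    step_length_a = list(predictors = c("updrs3", "sex_f", "baseline"),
                         coefs = c(0.409, -0.006, -0.056, -0.413),
                         sigma = 0.05, applied = TRUE),
    step_length_na = list(predictors = c("updrs3", "sex_f", "baseline"),
                          coefs = c(0.421, -0.005, -0.077, -0.297),
                          sigma = 0.05, applied = TRUE),
    trunk_transverse = list(predictors = c("hy_stage", "disease_duration",
                                           "age", "baseline"),
                            coefs = c(39.059, -2.170, 0.392, -0.387, -0.955),
                            sigma = 4.5, applied = TRUE)
  )
}

#' Cohort generation configuration
#'
#' @param n_patients,n_controls group sizes (defaults 36 / 22).
#' @param n_trials_per_session walking trials per subject-session (>= 6).
#' @param sampling_rate marker sampling frequency, Hz.
#' @param noise_sd_marker additive marker noise SD, mm.
#' @param seed integer seed; the same config + seed reproduces the cohort
#'   bit for bit.
#' @param params group-level moments, see [default_param_moments()]; SDs
#'   must be positive.
#' @param regression_truth see [default_regression_truth()].
#' @param session_correlation within-subject correlation of a variable
#'   across sessions for variables not governed by the regression truth.
#' @param trial_cv between-trial coefficient of variation of cadence and
#'   step lengths within a session.
#' @param p_normalize_asymmetry probability that a patient's spatial
#'   asymmetry normalizes (follow-up drawn from the control distribution).
#' @param control_speed_range relative speed range of control trials
#'   (controls walk at preferred and deliberately lower speeds, so their
#'   trial speeds span this multiplicative range).
#' @param center_changes when TRUE (default), the regression-truth intercepts
#'   are replaced so the mean change of each regression-driven outcome equals
#'   the configured baseline-to-follow-up group difference; the slope
#'   structure is untouched. When FALSE the configured intercepts are used
#'   verbatim.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 36, n_controls = 22,
                          n_trials_per_session = 6, sampling_rate = 300,
                          noise_sd_marker = 1, seed = 1,
                          params = default_param_moments(),
                          regression_truth = default_regression_truth(),
                          session_correlation = 0.7, trial_cv = 0.03,
                          p_normalize_asymmetry = 0.52,
                          control_speed_range = c(0.70, 1.15),
                          center_changes = TRUE) {
  if (n_trials_per_session < 6)
    stop("n_trials_per_session must be >= 6 (first trial is discarded, five analysed)")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  for (p in names(params)) for (g in names(params[[p]]))
    for (s in names(params[[p]][[g]]))
      if (params[[p]][[g]][[s]][2] <= 0)
        stop("non-positive SD for ", p, "/", g, "/", s)
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_trials_per_session = n_trials_per_session,
                 sampling_rate = sampling_rate,
                 noise_sd_marker = noise_sd_marker, seed = seed,
                 params = params, regression_truth = regression_truth,
                 session_correlation = session_correlation,
                 trial_cv = trial_cv,
                 p_normalize_asymmetry = p_normalize_asymmetry,
                 control_speed_range = control_speed_range,
                 center_changes = center_changes),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws clinical covariates and per-subject, per-session gait parameter
#' truths from the configured group distributions; patient follow-up values
#' of the predictable outcomes (cadence, both step lengths, trunk rotation
#' RoM) are constructed as linear functions of the clinical covariates per
#' `config$regression_truth` plus Gaussian noise; spatial asymmetry
#' normalizes with the configured probability. Per-trial parameter
#' realizations add between-trial jitter (and, for controls, the
#' deliberate slow-walking speed spread that makes speed matching
#' meaningful). Marker-level trajectories for every trial can be generated
#' on demand via [cohort_trial_profile()] and [generate_trial()].
#'
#' @param config a [cohort_config()].
#' @return list of class `gait_cohort`: `clinical` (one row per subject),
#'   `sessions` (ground-truth parameters per subject-session, including
#'   derived speed and native-unit changes for the regression-driven
#'   outcomes), `trials` (per-trial parameter realizations), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_patients; nc <- config$n_controls
  n <- np + nc
  rho <- config$session_correlation

  tnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    x <- rnorm(n, mean, sd)
    pmin(pmax(x, lower), upper)
  }
  clinical <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("patient", "control"), c(np, nc)),
    affected_side = c(sample(c("left", "right"), np, replace = TRUE),
                      rep("right", nc)),  # controls: dominant side
    age = round(c(tnorm(np, 68.83, 9.85, 40, 90),
                  tnorm(nc, 65.6, 5.0, 57, 75)), 1),
    sex_f = c(rbinom(np, 1, 16 / 36), rbinom(nc, 1, 10 / 22)),
    disease_duration = round(c(tnorm(np, 7.56, 4.15, 0.5, 25), rep(0, nc)), 1),
    updrs2 = round(c(tnorm(np, 12.61, 7.19, 0, 40), rep(0, nc)), 0),
    updrs3 = round(c(tnorm(np, 15.78, 6.89, 1, 50), rep(0, nc)), 0),
    hy_stage = c(sample(1:3, np, replace = TRUE, prob = c(0.25, 0.24, 0.51)),
                 rep(0, nc)),
    led = round(c(tnorm(np, 571.92, 317.2, 0, 2000), rep(0, nc)), 0),
    stringsAsFactors = FALSE)
  clinical$sex <- ifelse(clinical$sex_f == 1, "F", "M")

  pm <- config$params
  draw_pair <- function(param, group) {
    mb <- pm[[param]][[group]]$baseline; mf <- pm[[param]][[group]]$followup
    zs <- rnorm(1); zb <- rnorm(1); zf <- rnorm(1)
    c(baseline = mb[1] + mb[2] * (rho * zs + sqrt(1 - rho^2) * zb),
      followup = mf[1] + mf[2] * (rho * zs + sqrt(1 - rho^2) * zf))
  }
  lowers <- c(cadence = 40, mean_step = 0.15, asymmetry = 0.2, stance = 52,
              step_width = 0.05, hip_rom_a = 5, hip_rom_na = 5,
              knee_rom_a = 10, knee_rom_na = 10, ankle_rom_a = 5,
              ankle_rom_na = 5, trunk_sagittal = 0.5, trunk_frontal = 0.5,
              trunk_transverse = 0.5)

  rows <- list()
  for (i in seq_len(n)) {
    grp <- clinical$group[i]
    vals <- sapply(names(pm), function(p) {
      v <- draw_pair(p, grp)
      pmax(v, lowers[[p]])
    })
    base <- setNames(vals["baseline", ], colnames(vals))
    fup  <- setNames(vals["followup", ], colnames(vals))
    # side step lengths from mean step + asymmetry (affected side shorter)
    split_steps <- function(mean_step, asym) {
      mean_step <- unname(mean_step); asym <- unname(asym)
      r <- 1 - min(asym, 60) / 100
      c(a = 2 * mean_step * r / (1 + r), na = 2 * mean_step / (1 + r))
    }
    sb <- split_steps(base["mean_step"], base["asymmetry"])
    sf <- split_steps(fup["mean_step"], fup["asymmetry"])

    row_for <- function(session, v, steps) {
      data.frame(subject_id = clinical$subject_id[i], group = grp,
                 session = session,
                 cadence = v[["cadence"]],
                 step_length_a = steps[["a"]], step_length_na = steps[["na"]],
                 asymmetry = spatial_asymmetry(steps[["a"]], steps[["na"]]),
                 stance_a = v[["stance"]], stance_na = v[["stance"]],
                 step_width = v[["step_width"]],
                 hip_rom_a = v[["hip_rom_a"]], hip_rom_na = v[["hip_rom_na"]],
                 knee_rom_a = v[["knee_rom_a"]], knee_rom_na = v[["knee_rom_na"]],
                 ankle_rom_a = v[["ankle_rom_a"]], ankle_rom_na = v[["ankle_rom_na"]],
                 trunk_sagittal = v[["trunk_sagittal"]],
                 trunk_frontal = v[["trunk_frontal"]],
                 trunk_transverse = v[["trunk_transverse"]],
                 stringsAsFactors = FALSE)
    }
    rb <- row_for("baseline", base, sb)
    rf <- row_for("followup", fup, sf)

    rows[[length(rows) + 1]] <- rb
    rows[[length(rows) + 1]] <- rf
  }
  sessions <- do.call(rbind, rows)
  rownames(sessions) <- NULL

  # regression-driven patient follow-up values: change = X beta + noise.
  # Slopes are the configured truth; when centre_changes is on the
  # intercept is replaced so the mean change equals the configured
  # baseline-to-follow-up group difference (the printed intercepts are not
  # jointly consistent with the printed group means under independently
  # drawn covariates).
  pat_b <- which(sessions$group == "patient" & sessions$session == "baseline")
  pat_f <- which(sessions$group == "patient" & sessions$session == "followup")
  clin_p <- clinical[match(sessions$subject_id[pat_b], clinical$subject_id), ]
  split_steps_v <- function(mean_step, asym) {
    r <- 1 - pmin(asym, 60) / 100
    list(a = 2 * mean_step * r / (1 + r), na = 2 * mean_step / (1 + r))
  }
  fu_targets <- local({
    st <- split_steps_v(pm$mean_step$patient$followup[1],
                        pm$asymmetry$patient$followup[1])
    c(cadence = pm$cadence$patient$followup[1],
      step_length_a = st$a, step_length_na = st$na,
      trunk_transverse = pm$trunk_transverse$patient$followup[1])
  })
  for (outcome in c("cadence", "step_length_a", "step_length_na",
                    "trunk_transverse")) {
    tr <- config$regression_truth[[outcome]]
    if (is.null(tr) || !isTRUE(tr$applied)) next
    base_v <- sessions[[outcome]][pat_b]
    X <- vapply(tr$predictors, function(p)
      if (p == "baseline") base_v else clin_p[[p]], numeric(np))
    lp <- as.numeric(X %*% tr$coefs[-1])
    change <- if (isTRUE(config$center_changes))
      lp - mean(lp) + (fu_targets[[outcome]] - mean(base_v)) +
        rnorm(np, 0, tr$sigma)
    else tr$coefs[1] + lp + rnorm(np, 0, tr$sigma)
    lo <- if (grepl("step", outcome)) 0.10 else
      lowers[[sub("step_length_.*", "mean_step", outcome)]]
    sessions[[outcome]][pat_f] <- pmax(base_v + change, lo)
  }
  # asymmetry normalization mixture: redistribute the follow-up step lengths
  # around their mean to hit the target asymmetry, keeping the affected side
  # the shorter one as at baseline
  cm <- pm$asymmetry$control$followup
  normalizes <- runif(np) < config$p_normalize_asymmetry
  target_asym <- ifelse(normalizes, abs(rnorm(np, cm[1], cm[2])),
                        pmax(sessions$asymmetry[pat_b] *
                               rnorm(np, 1, 0.25), 0.2))
  mfu <- (sessions$step_length_a[pat_f] + sessions$step_length_na[pat_f]) / 2
  st <- split_steps_v(mfu, target_asym)
  sessions$step_length_a[pat_f] <- st$a
  sessions$step_length_na[pat_f] <- st$na
  sessions$asymmetry[pat_f] <- spatial_asymmetry(st$a, st$na)
  sessions$speed <- (sessions$step_length_a + sessions$step_length_na) / 2 *
    sessions$cadence / 60

  # per-trial realizations (vectorized over sessions x trials)
  cv <- config$trial_cv
  K <- config$n_trials_per_session
  idx <- rep(seq_len(nrow(sessions)), each = K)
  N <- length(idx)
  is_ctrl <- sessions$group[idx] == "control"
  u <- ifelse(is_ctrl,
              runif(N, config$control_speed_range[1],
                    config$control_speed_range[2]), 1)
  jit <- function(x, s) x * rnorm(N, 1, s)
  cad <- jit(sessions$cadence[idx], cv) * sqrt(u)
  sa <- jit(sessions$step_length_a[idx], cv) * sqrt(u)
  sna <- jit(sessions$step_length_na[idx], cv) * sqrt(u)
  trials <- data.frame(
    subject_id = sessions$subject_id[idx], group = sessions$group[idx],
    session = sessions$session[idx], trial = rep(seq_len(K), nrow(sessions)),
    cadence = cad, step_length_a = sa, step_length_na = sna,
    stance_a = pmin(pmax(sessions$stance_a[idx] + rnorm(N, 0, 0.4), 52), 74),
    stance_na = pmin(pmax(sessions$stance_na[idx] + rnorm(N, 0, 0.4), 52), 74),
    step_width = pmax(jit(sessions$step_width[idx], cv), 0.03),
    hip_rom_a = jit(sessions$hip_rom_a[idx], 0.02),
    hip_rom_na = jit(sessions$hip_rom_na[idx], 0.02),
    knee_rom_a = jit(sessions$knee_rom_a[idx], 0.02),
    knee_rom_na = jit(sessions$knee_rom_na[idx], 0.02),
    ankle_rom_a = jit(sessions$ankle_rom_a[idx], 0.02),
    ankle_rom_na = jit(sessions$ankle_rom_na[idx], 0.02),
    trunk_sagittal = jit(sessions$trunk_sagittal[idx], 0.02),
    trunk_frontal = jit(sessions$trunk_frontal[idx], 0.02),
    trunk_transverse = jit(sessions$trunk_transverse[idx], 0.02),
    stringsAsFactors = FALSE)
  trials$speed <- (trials$step_length_a + trials$step_length_na) / 2 *
    trials$cadence / 60
  structure(list(clinical = clinical, sessions = sessions, trials = trials,
                 config = config),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("<gait_cohort>", x$config$n_patients, "patients +",
      x$config$n_controls, "controls, 2 sessions,",
      x$config$n_trials_per_session, "trials each\n")
  invisible(x)
}

#' Gait profile of one cohort trial
#'
#' Builds the [gait_profile()] realizing the trial-level parameter row of a
#' generated cohort, for marker-level trajectory generation with
#' [generate_trial()].
#'
#' @param cohort a `gait_cohort`.
#' @param subject_id,session,trial identifiers of the trial row.
#' @return a `gait_profile`.
#' @export
cohort_trial_profile <- function(cohort, subject_id, session, trial) {
  tr <- cohort$trials
  row <- tr[tr$subject_id == subject_id & tr$session == session &
              tr$trial == trial, ]
  if (nrow(row) != 1) stop("trial not found")
  gait_profile(
    step_length_a = row$step_length_a, step_length_na = row$step_length_na,
    cadence = row$cadence, stance_pct = c(row$stance_a, row$stance_na),
    step_width = row$step_width,
    hip_rom = c(row$hip_rom_a, row$hip_rom_na),
    knee_rom = c(row$knee_rom_a, row$knee_rom_na),
    ankle_rom = c(row$ankle_rom_a, row$ankle_rom_na),
    trunk_rom = c(row$trunk_sagittal, row$trunk_frontal, row$trunk_transverse))
}

#' Generate clinical covariates and one regression outcome directly
#'
#' Draws a clinical table (same distributions as [generate_cohort()]) plus a
#' baseline value, and constructs the outcome as `X beta + noise` from a
#' coefficient set — the minimal generator for regression-recovery studies.
#'
#' @param n number of patients.
#' @param predictors predictor names among `age`, `sex_f`,
#'   `disease_duration`, `updrs2`, `updrs3`, `hy_stage`, `led`, `baseline`.
#' @param coefs numeric, intercept first then one per predictor.
#' @param sigma residual SD.
#' @param baseline_mean,baseline_sd distribution of the `baseline` column.
#' @param seed optional seed.
#' @return data.frame with the covariates, `baseline` and `outcome`.
#' @export
generate_regression_data <- function(n, predictors, coefs, sigma,
                                     baseline_mean = 0.777,
                                     baseline_sd = 0.305, seed = NULL) {
  if (length(coefs) != length(predictors) + 1)
    stop("coefs must be intercept followed by one coefficient per predictor")
  if (!is.null(seed)) set.seed(seed)
  tnorm <- function(n, mean, sd, lower, upper)
    pmin(pmax(rnorm(n, mean, sd), lower), upper)
  d <- data.frame(
    age = tnorm(n, 68.83, 9.85, 40, 90),
    sex_f = rbinom(n, 1, 16 / 36),
    disease_duration = tnorm(n, 7.56, 4.15, 0.5, 25),
    updrs2 = round(tnorm(n, 12.61, 7.19, 0, 40)),
    updrs3 = round(tnorm(n, 15.78, 6.89, 1, 50)),
    hy_stage = sample(1:3, n, replace = TRUE, prob = c(0.25, 0.24, 0.51)),
    led = tnorm(n, 571.92, 317.2, 0, 2000),
    baseline = pmax(rnorm(n, baseline_mean, baseline_sd), baseline_mean / 10))
  X <- as.matrix(d[, predictors, drop = FALSE])
  d$outcome <- coefs[1] + as.numeric(X %*% coefs[-1]) + rnorm(n, 0, sigma)
  d
}
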