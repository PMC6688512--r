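# pdgait

Gait responsiveness analysis for rehabilitation studies in Parkinson's
disease, from raw 3D marker trajectories to clinical decision thresholds.

Rehabilitation can improve the gait of people with Parkinson's disease, but
three questions matter to a clinician reading a gait report: which
parameters actually changed, how large a change is clinically meaningful,
and which patients are likely to improve. `pdgait` implements the full
analysis chain a speed-matched case-control rehabilitation study uses to
answer them:

- **Kinematics** — gap interpolation, zero-lag low-pass Butterworth
  filtering (6 Hz, 2nd order per pass, effective 4th order),
  coordinate-based heel-strike/toe-off detection (extrema of the heel/toe
  anterior position relative to the sacrum), steady-state step selection
  (first trial discarded, two central steps per side of five trials — about
  20 steps per subject and session), joint and trunk angle reconstruction.
- **Gait parameters** — cadence, walking speed, per-side stance and initial
  double-support percentages, step length/width, sagittal hip/knee/ankle
  RoMs, trunk RoM in three planes, and the spatial asymmetry index

  `asymmetry = (1 − min(A, NA) / max(A, NA)) · 100`

  where `A`/`NA` are the step lengths of the most/least affected sides.
- **Cohort statistics** — control-trial speed matching to the patient mean
  ± SD band, percent change `Δ = 100 · (value_10week − value_baseline) /
  value_baseline`, Shapiro-Wilk-gated Student-t / Mann-Whitney (and paired
  t / Wilcoxon) comparisons with Cohen's d, improvement classification
  against control means, chi-square of improved proportions, gated
  Pearson/Spearman correlations, and noncentral-t paired power analysis.
- **Responsiveness (anchor-based MCID)** — normalization anchors (improved
  *and* within k·SD of the control mean), empirical ROC with Mann-Whitney
  AUC and DeLong confidence intervals, minimal clinically important
  difference by the smallest `(1−Se)² + (1−Sp)²` criterion, likelihood
  ratios, predictive values and Fagan post-test probabilities.
- **Prediction** — backward-selection multiple linear regression of Δ
  outcomes on baseline clinical covariates (age, sex, disease duration,
  UPDRS-II/III, Hoehn-Yahr stage, levodopa-equivalent dose, and the
  protected baseline value of the outcome), with Durbin-Watson, VIF,
  Breusch-Pagan, residual-normality and outlier diagnostics.
- **Synthetic gait generator** — a 13-marker forward model of overground
  walking (footfall schedule plus two-harmonic joint-angle templates) and a
  cohort generator with configurable group distributions and a known
  clinical-covariate → Δ regression structure, so every stage is testable
  against ground truth without any recorded data.

Marker I/O uses a long-format CSV (`trial, frame, marker, x, y, z`,
millimetres or metres, auto-detected); the walking direction is
auto-detected from the sacrum path.

## Worked example

```r
library(pdgait)

# a patient-like walking pattern: short affected-side step, fast cadence
p <- gait_profile(step_length_a = 0.38, step_length_na = 0.46, cadence = 104,
                  stance_pct = 63, hip_rom = c(31, 34), knee_rom = c(45, 49),
                  ankle_rom = 24, trunk_rom = c(3.4, 4.0, 7.0))
tr  <- generate_trial(p, seed = 1, affected_side = "left")
ses <- extract_session(rep(list(tr$traj), 6))   # one session's six trials
aggregate_session(ses$per_trial, subject_id = "P01", affected_side = "left")
#>   cadence speed_mps step_length_m_a step_length_m_na spatial_asymmetry_pct
#>    104.05      0.73            0.38             0.46                 17.59
#>   hip_rom_a knee_rom_na trunk_rom_transverse n_steps_used
#>       31.09       49.05                 7.02           20
```

The pipeline recovered the generating pattern from the noisy markers:
cadence 104 steps/min, speed 0.73 m/s, the 0.38/0.46 m step lengths (hence
a 17.6 % spatial asymmetry), the joint RoMs, and exactly 20 retained steps.

The responsiveness arithmetic turns a classifier row into clinical numbers:

```r
d <- diagnostic_stats(se = 0.9474, sp = 0.8824, prevalence = 19/36)
sprintf("LR+ = %.2f, PV+ = %.1f%%", d$lr_pos, 100 * d$pv_pos)
#> "LR+ = 8.06, PV+ = 90.0%"

paired_power_sample_size(effect_size_d = 0.5, power = 0.80, alpha = 0.05)
#> 34
```

So a patient whose spatial asymmetry dropped beyond the MCID has a 90 %
post-test probability of having normalized it, and 34 participants suffice
to detect a medium paired effect at 80 % power.

`run_pipeline(analysis_config(seed = 1))` executes the whole chain —
simulate, extract, match, compare, MCID, predict — and writes
`parameters.csv`, `comparisons.csv`, `deltas.csv`, `mcid.json`,
`regression.json` and `run.log` to the output directory. A thin CLI wrapper
lives at `inst/scripts/run-pipeline.R`.

## Documentation

The methods vignette (`vignettes/gait-responsiveness.Rmd`) describes the
model and its assumptions, what the synthetic generator does and does not
emulate, all numerical choices and known limitations.
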