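---
title: "Measuring and predicting gait responsiveness to rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting gait responsiveness to rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgait)
```

## The analysis this package implements

A rehabilitation gait study of people with Parkinson's disease compares
patients with healthy controls before and after a treatment period, then
asks three questions: which gait parameters differ and change; how large a
percent change in a normalizable parameter is clinically meaningful (the
minimal clinically important difference, MCID); and which baseline clinical
characteristics predict improvement. `pdgait` implements that chain as
composable functions plus a `run_pipeline()` driver, with a synthetic data
generator supplying ground truth for every stage.

The laboratory frame is +Y anterior, +Z vertical, +X to the subject's
right; positions are millimetres internally, metres in reports. Readers and
the event detector auto-detect the anterior axis from the sacrum path (axis
of largest excursion, sign from net displacement), so recordings in any
orientation, walking either way, are handled identically.

## From markers to gait parameters

**Filtering.** Marker trajectories are gap-interpolated linearly (gaps at
most 0.1 s; longer gaps reject the trial) and low-pass filtered with a
zero-lag Butterworth filter at 6 Hz. "Fourth-order zero-lag" follows the
dominant biomechanics convention: a 2nd-order filter run forward and
backward, giving an effective 4th-order magnitude response with gain 0.5 at
the cut-off; a strict 4th-order-per-pass mode is available
(`per_pass = "full"`). Edge transients are controlled by odd-reflection
padding of three cut-off periods and by filtering each pass's deviations
from its first sample, so a constant signal passes through exactly.

**Events.** Heel strike is a local maximum of the heel's anterior position
relative to the sacrum; toe-off is the minimum of the toe's relative
anterior position between two consecutive same-side heel strikes. The
method needs no force plates and is verifiable against the simulator's
ground-truth footfall schedule; a velocity-threshold fallback is provided
behind the `method` flag. Peaks must rise above mid-range by a configurable
prominence fraction (default 0.25) and closer-than-half-a-stride duplicates
are pruned; fewer than three heel strikes on a side rejects the trial.
Alternation (HS, TO, HS, ...) holds by construction because toe-offs are
searched strictly between heel-strike pairs.

**Steady state.** Per subject-session the first trial is discarded and the
next five analysed; per side of each trial the first and last two steps
(acceleration/deceleration) are excluded and the central two retained —
with six 8-stride trials this yields the canonical ~20 steps per
subject-session. When the usable step count is odd the central pair ties
toward the later pair; a trial with fewer than six steps on a side (too few
to trim and still keep a central pair) is excluded and logged. Frame
windows are half-open step intervals `[contralateral HS, own HS]`.

**Spatio-temporal parameters.** Stance is (toe-off − heel strike) as a
percentage of the stride containing the retained step; initial double
support is the interval from a heel strike to the next contralateral
toe-off, also as % of stride, and is labelled per-side *initial* double
support (whether a report's double-support values are per-side initial or
halved total is rarely stated; this package states its choice). Step length
and width are anterior/mediolateral distances between heel positions of
successive contralateral heel strikes. Because a zero-phase filter rounds
the landing kink of the heel trajectory, heel positions are sampled 40 ms
after each contact (`stabilize_s`), when the filter has settled on the
foot-flat position and both feet are still grounded — initial double
support lasts longer than 40 ms at walking cadences. Cadence comes from the
mean retained step duration; speed from the sacrum's anterior displacement
across the retained windows.

**Angles.** Only sagittal lower-limb angles are reported (the
flexion-extension axis of a mediolateral-first rotation sequence, which
limits sensitivity to the remaining sequence choices): hip as thigh versus
pelvis vertical, knee as thigh-minus-shank flexion, ankle as foot (heel to
toe) pitch relative to the shank. The hip centre is reconstructed from the
sacrum, the ASIS-line yaw and the shared body-model offsets of
`gait_marker_model()`, scaled by the subject's inter-ASIS distance, which
makes all angles invariant to body size (the package's analogue of
anthropometric scaling tables). Trunk angles are the sacrum-C7 axis versus
vertical (sagittal/frontal) and the acromion line versus the laboratory
mediolateral axis (transverse). RoM is max − min over the union of
retained windows; a degenerate (zero-length) segment is an error.

**Aggregation.** Subject-session values are means over retained
steps/trials. The spatial asymmetry index
`100·(1 − min/max)` is computed on the per-side *mean* step lengths
(stable for ~20 steps); the mean of per-step asymmetries is reported
alongside, since the two differ on heterogeneous steps. Controls have no
affected side; their sides are mapped dominant/non-dominant and the index,
being side-agnostic, is still defined.

## Cohort statistics

Speed matching keeps, per session, the control trials whose speed lies in
the closed patient-group mean ± SD band, and drops (with a log entry)
controls with no surviving trial; matching is against the whole patient
group, not per pair. Percent change uses
`Δ = 100·(follow-up − baseline)/baseline`. Group and session comparisons
are gated by Shapiro-Wilk at α = 0.05 per sample (the gate level is a
package choice; comparison tables rarely print it): Student's
pooled-variance t (not Welch — the pooled form is what reproduces printed t
values from group moments) or Mann-Whitney U, paired t or Wilcoxon.
Cohen's d uses the pooled-SD (unpaired) or SD-of-differences (paired)
definition with an absolute-value convention; published effect-size columns
are not always reproducible from printed moments under any single standard
formula, and this package documents its own rather than chasing such cells.
Improvement means the follow-up value is strictly closer to the control
mean than baseline was (ties, within a 1e-9 relative guard, count as not
improved — the conservative choice), and the improved proportion is tested
against an even split by a 1-df chi-square without continuity correction.
The paired power analysis searches the smallest n whose noncentral-t power
reaches the target; at d = 0.5, α = 0.05 two-sided and 80% power it returns
n = 34 pairs.

## Anchor-based responsiveness

A patient *normalizes* a variable when they improved **and** the follow-up
value lies on the healthy side of `control mean ± k·SD` (k default 1,
configurable): "reached control values" needs an operational definition,
and a one-SD band is the common practice. The Δ values are then scored
against this anchor: the empirical ROC's AUC equals the Mann-Whitney
concordance probability, oriented so AUC ≥ 0.5 with the orientation
reported (for lower-is-better variables the score is the reduction, so the
MCID reads "reduction > cut-off"). Candidate cut-offs are midpoints between
sorted distinct scores plus outer sentinels — the "criterion > t"
convention of clinical ROC software. The optimal MCID minimizes
`(1−Se)² + (1−Sp)²`; ties break toward higher sensitivity, then the higher
threshold. The AUC confidence interval is DeLong's placement-value
interval, cross-checked in the test suite against an independent
implementation (`pROC`). Likelihood ratios (`LR+ = Se/(1−Sp)`, reported as
`Inf` when Sp = 1), predictive values at the observed prevalence, and
Fagan-nomogram post-test probabilities (pre-test odds × LR, back to a
probability) complete the responsiveness row.

## Prediction

Each Δ outcome is regressed on baseline clinical covariates by backward
elimination: drop the largest-p predictor above `removal_alpha`, refit,
repeat. `removal_alpha` defaults to 0.10 rather than 0.05 because published
models of this kind retain terms with p ≈ 0.06; the outcome's own baseline
value is always offered and never dropped (every published block retains
it). Ties in the removal p break lexicographically, making the procedure
invariant to predictor ordering. Sex is coded male = 0 / female = 1
(`SEX_CODING`), so a negative coefficient on `sex_f` means men improve
more; the coding is a package constant precisely because "Gender (F/M)"
labels are ambiguous. Standard (non-robust) errors match the era's default
statistical software. Diagnostics cover Durbin-Watson, VIFs, residual
Shapiro-Wilk, Breusch-Pagan, and |studentized residual| > 3 outliers.

## What the synthetic generator emulates

`generate_trial()` is a measurement-oriented forward model of the
13-marker set (sacrum, ASIS, lateral knee, lateral malleolus, heel, toe,
acromion, C7 — a deliberate reduction of full laboratory marker sets to
exactly the markers the computed variables need). Foot markers follow an
explicit footfall schedule — feet stationary in stance, smooth swing
transport — so step lengths, widths, stance percentages and event times are
exact by construction; sampling is 300 Hz and marker noise defaults to
1 mm SD white Gaussian per coordinate (the order of optical spatial
accuracy plus soft-tissue artifact). The swing velocity template keeps
non-zero lift-off/touch-down velocity (about twice the progression speed),
which leaves sharp extrema in the heel/toe-relative-to-sacrum signals at
the true events even after 6 Hz filtering. Pelvis, leg-chain and trunk
markers are driven by two-harmonic joint-angle templates scaled to the
profile's RoMs; since only max − min is consumed downstream, the template
shape is otherwise free, and the knee phase is kept close to the hip's so
the shank (and hence foot-pitch) excursion stays moderate. The profile
enforces the identity `speed = mean step × cadence / 60` to 1e-9, and
symmetric left/right phasing implies initial double support =
stance − 50 %.

The generator is not a physical digital twin: the ankle joint is not
closed (foot markers obey the footfall schedule, leg-chain markers the
angle templates), there is no force, muscle or balance model, no
freezing-of-gait episodes, no arm swing beyond the trunk markers, and no
treadmill mode. Passing round-trip tests therefore demonstrates that the
measurement chain inverts this forward model to its stated tolerances —
steps/cadence within 1 %, RoMs within 0.5°, events within 3 frames
noise-free — not that it reproduces any particular laboratory's
event-detection rule or biomechanical model, whose original definitions
are not public.

`generate_cohort()` draws 36 patients and 22 controls (configurable) with
two sessions and six trials each. Group distributions default to the
published patient/control, baseline/follow-up moments of each parameter;
cadence, mean step length and the asymmetry index are drawn and the two
side step lengths and speed derived, because a printed table's speed, step
and cadence rows need not satisfy the speed identity exactly and the
generator must. Within-subject session correlation is 0.7, between-trial
variation 3 % CV, both chosen as realistic test-retest figures. Controls'
trial speeds are spread multiplicatively over 0.70-1.15 of their session
speed — they walk at preferred and deliberately slower speeds — which is
what gives speed matching something to do. Patient follow-up values of the
four predictable outcomes (cadence, both step lengths, trunk rotation RoM)
are `baseline + Xβ + noise` with the published slope sets; the intercepts
are re-centred so each outcome's mean change equals the configured
session difference, because the published intercepts and the published
group means are not jointly consistent when covariates are drawn
independently (the real covariates were correlated in ways a table does
not record). Setting `center_changes = FALSE` uses the printed intercepts
verbatim; `generate_regression_data()` always does, and is the generator
used for coefficient-recovery studies. ΔSpeed is emergent (speed is
derived), so its published coefficient set is carried as configuration but
exercised through `generate_regression_data()`. Spatial asymmetry
normalizes with probability 0.52 (follow-up drawn from the control
follow-up distribution, the two follow-up step lengths redistributed
around their mean to realize it); trunk-rotation normalization is emergent
from its regression truth.

## Numerical choices and degenerate inputs

- Frame indexing is 1-based (R convention); step windows are
  `[contralateral HS, own HS]` and event frames are rounded to the nearest
  sample.
- Filter warm-up requires at least three filter lengths of samples; the
  interpolation rejects boundary gaps (nothing to anchor a linear fill).
- The asymmetry index rejects non-positive step lengths; `delta_pct`
  rejects a zero baseline; `diagnostic_stats` reports `LR+ = Inf` at
  Sp = 1 rather than failing.
- Rank tests use exact p-values at small n and the normal approximation
  (with continuity correction, via R's defaults) at larger n.
- The cohort generator truncates draws at physiologic floors (e.g.
  cadence ≥ 40 steps/min, asymmetry ≥ 0.2 %) so downstream percent changes
  stay defined; the truncation bias is negligible except for the
  asymmetry index, whose configured SD is near its mean.
- `run_pipeline()` runs at two levels: `"markers"` simulates and
  re-extracts every trial through the full measurement chain;
  `"parameters"` analyses the per-trial parameter realizations directly.
  Both share all downstream statistics and are deterministic for a fixed
  seed.

The test suite exercises the stages at deliberately moderate problem
sizes — e.g. 100 noise-free trials for the round-trip study, 50-200 seeds
for the Monte-Carlo checks, 1,000 random instances for the ROC/MCID
brute-force equivalences, 10,000 replicates for the type-I error
calibration, and marker-level pipelines of a handful of subjects — sizes
at which the targeted properties are already sharply testable.

## Known limitations

- C3D files are not read or written; marker I/O is long-format CSV. The
  structure mirrors what a C3D import would supply, so adding a reader is
  a contained extension.
- Only sagittal lower-limb angles are computed; no frontal/transverse
  joint angles, no inverse dynamics, no gait-variability or arm-swing
  metrics.
- The anchor definition ("reached control values") and the exact
  event-detection rule of the emulated laboratory are operationalized, not
  reconstructed; equivalence claims are against the simulator only.
- No multiple-testing correction is applied across the comparison table by
  default (matching the emulated analysis); a Bonferroni flag would be a
  one-line extension around the comparison loop.
- The DeLong interval is asymptotic; with a handful of subjects per class
  its coverage is approximate, and an exact binomial option is not
  provided.
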