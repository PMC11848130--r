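---
title: "Methods: first-three-steps gait analysis and fall-risk model development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-three-steps gait analysis and fall-risk model development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tristep implements a complete workflow for screening fall risk from the
first three steps of a standing-start walk, recorded as 33-point
pose-landmark time series (the topology of common monocular pose engines).
This vignette explains the models and procedures, the tunable parameters,
the synthetic-data generator used to validate every stage, and the design
choices made where the problem left the design open.

## 1. Coordinates, landmarks and composite joints

All pose data live in a right-handed world frame with y vertical (up), z
the walking direction and x to the walker's left, in meters. A
`pose_sequence` holds one trial: frame times, an `n x 33 x 3` coordinate
array, optional per-landmark visibilities, and trial metadata (participant,
sex, stature, fall-history label, trial index, cohort). Composite joints
that the 33-point topology lacks are derived per frame as means of measured
points: `mid_hip`, `mid_shoulder`, `trunk_center` (shoulders + hips), and
`head_center`, defined here as the centroid of the nose and both ears - a
symmetric choice available in the topology.

Pose engines emitting normalized image coordinates can be rescaled by
stature on ingestion; since every distance feature is stature-normalized
downstream, only relative scale matters, but meters keep simulator ground
truth interpretable. Sequences with more than 1% timing jitter are linearly
resampled to a uniform grid (`resample_uniform`), because all
differentiation assumes uniform sampling. Short dropped-landmark gaps
(<= `max_gap` frames, interior only) are filled by linear interpolation and
reported; boundary gaps are never extrapolated.

## 2. Kinematics

Trajectories are smoothed by a 4th-order zero-phase Butterworth low-pass
(`signal::filtfilt`, applied forward and backward) with a 6 Hz default
cutoff - gait kinematics live below ~6 Hz, and minima-picking on raw
differentiated noise is unstable. The series is demeaned and
reflection-padded before filtering so a constant series passes through
exactly (unit DC gain). Velocities use central differences (one-sided at
the ends), exact for linear ramps.

Two angle constructions cover all angular features:

* **internal angle** - the 3-point vertex angle (e.g. hip-knee-ankle for
  the knee), in [0, 180] degrees, invariant to rigid motion;
* **external angle** - the signed angle of a 2-point body vector against a
  global axis after projection into a named body plane (sagittal = y-z,
  frontal = x-y, transverse = z-x), sign by the right-hand rule about the
  plane normal.

Angles are reported in degrees throughout, matching clinical ROM usage.
Waveform statistics over an interval use the population standard deviation:
the frames are the whole waveform, not a sample from it.

## 3. Gait cycle segmentation

A gait cycle runs from one foot's ground contact to that same foot's next
contact. Heel strikes are identified on the *vertical ankle velocity*: the
foot descends fastest just before contact, so contacts appear as sharp
local minima of that signal.

The detector works in three stages:

1. **Gait interval.** Forward mid-hip speed, smoothed at 6 Hz, must exceed
   0.1 m/s continuously for 0.2 s; the first such run starts the gait
   (onset), the last one ends it. Candidate events are gated to this
   interval (plus 0.3 s for the landing of the final step) - quiet standing
   before and after the walk otherwise contributes spurious noise dips.
2. **Candidates.** Local minima of the 5 Hz-smoothed vertical ankle
   velocity, with prominence at least 10% of the in-gait interquartile
   range, separation at least 0.3 s, and depth at least 40% of the deepest
   in-gait descent. The prominence and separation rules reject small
   wiggles at normal cadences; the depth gate removes shallow dips left by
   filter undershoot and residual noise.
3. **Refinement.** Around each candidate the velocity steps sharply at the
   event (descent ends at a strike; ascent begins at a toe-off). On a
   lightly smoothed (8 Hz) velocity, the half-amplitude crossing of a
   zero-phase-smoothed step sits at the step itself, so each event time is
   the interpolated half-crossing - sub-frame, and robust to noise because
   the crossing lies on the steepest part of the edge. Toe-off is the
   maximum upward ankle velocity between consecutive same-side strikes
   (before the first strike, a look-back window of one swing covers the
   lead-in), a standard kinematic proxy that needs no force plate.

Step k is the cycle starting at the k-th heel strike after onset,
whichever foot makes it - with alternating feet this matches "first three
steps" counting. Stance runs to the same-side toe-off, swing from there to
the cycle's closing strike; total double support sums the intervals where
both feet are in stance (a foot whose first event is a toe-off is taken to
have stood from the start of the record - the standing start). On
noise-free simulator output the recovered strike times are within ~5 ms of
truth and cycle durations within a frame period; with landmark noise at
0.5% of stature, event F1 at 50 ms tolerance exceeds 0.95 under the
study-range gait parameters. Detection degrades gracefully for walkers
combining very low foot lift with slow cadence; trials whose segmentation
fails are flagged and excluded by the missing-data policy rather than
guessed at.

## 4. The 77-feature catalogue

Per step (1-3), one set of recipes is instantiated: 3 speed/acceleration
features, 5 temporal, 7 distance/height (6 at step 1: stride length needs a
previous same-side contact), 11 angular - 77 in total. The catalogue is a
catalogue covering the spatiotemporal and angular quantities that
fall-risk gait studies report for initiation gait: head sway, swing time,
swing phase ratio, hip/knee ROM, head angle, maximum heel height, stride,
body sway, stance time, vertical trunk movement and trunk sway all appear.
Notable recipe decisions:

* *Walking speed* is the forward displacement of the cycle-side foot over
  the cycle divided by its duration; *max swing velocity* and *peak swing
  acceleration* are swing-phase extrema of that foot's forward velocity
  and acceleration.
* *Maximum heel height* and *toe clearance* are measured above the foot's
  own stance-phase baseline (median height while the foot is planted), so
  they are clearances - invariant to vertical translation of the world
  frame, which a raw peak height would not be.
* *Body sway* and *trunk sway* are treated as names for the same quantity:
  the lateral range of the trunk center.
* ROMs are taken over the full cycle, not only swing - "ROM" is used here
  without a phase qualifier.
* Head and trunk angles are measured against the vertical in the sagittal
  plane; pelvic obliquity and rotation against the x axis in the frontal
  and transverse planes - the conventional planes for these quantities.
* Normalization: displacements and heights are divided by stature,
  velocities by the square root of stature (pendular scaling of a
  rigid-link body), and accelerations by stature to extend the same
  dimensional scheme; all three are configurable. Angles, times and
  ratios pass through.

Aggregation to participant level averages the (up to three) trials.
Two derived families are emitted as supplementary columns, not part of the
77: the left-minus-right difference of each feature over the cycle sides
among steps 1-3, and the step1-minus-step2 difference (asymmetry and
initiation-transient summaries). Trials missing any feature are excluded
from modelling (missing-data exclusion policy).

## 5. Fall-risk model development

Model development runs separately per sex, on trial-level rows grouped by
participant (three rows per person; the outcome is participant-level).

1. **Univariate screening.** Each feature is scored by direction-agnostic
   discrimination `max(AUC, 1 - AUC)` against fall history; the top ~10
   are kept (raw AUCs reported; a feature at 0.44 genuinely outranks one
   at 0.52, since 0.56 > 0.52 after direction folding). Constants score
   0.5 and rank last; ties break by name.
2. **NearMiss undersampling (version 1, 3 neighbours).** With roughly 1:9
   positives to negatives and ~100 participants per sex, oversampling is
   unattractive; NearMiss-1 retains, per the chosen positive-to-negative
   ratio (1:4 by default), the negatives whose mean standardized Euclidean
   distance to their nearest positives is smallest. Ties break by row
   index, so selection is deterministic; version 1 with 3 neighbours is
   the canonical default of the NearMiss family.
3. **Stratified group k-fold.** Participants are assigned whole to folds
   (no splitting a person's trials), positives spread as evenly as
   achievable (within one group of perfect balance); deterministic per
   seed.
4. **Exhaustive combination search.** Every 3-, 4- and 5-feature
   combination of the screened candidates is evaluated under 6 CV runs
   (fold counts 3, 4, 5 x seeds 0, 1). Within each training fold only -
   never on held-out rows - NearMiss selects the training sample and
   standardization constants are estimated; a logistic model is fit and
   held-out rows are scored once per run. The combination score is the
   mean pooled PR-AUC across runs (PR-AUC is the metric of choice at rare
   outcomes; its random baseline is the prevalence). Ties prefer fewer
   features, then lexicographic order. The final model refits on the full
   NearMiss-resampled training data.
5. **Logistic model.** Maximum likelihood by IRLS (tolerance 1e-8, at most
   100 iterations) on standardized features; detected separation
   (non-convergence or runaway coefficients) triggers a flagged refit with
   a small ridge penalty (1e-4) so coefficients stay finite.
6. **External validation.** ROC-AUC with a DeLong 95% CI (via pROC) and
   PR-AUC with a stratified bootstrap percentile CI (2000 resamples, fixed
   seed); both are the standard choices for these metrics. AUCs carry
   interpretation bands:
   [0.9, 1] excellent, [0.8, 0.9) very good, [0.7, 0.8) good, [0.6, 0.7)
   sufficient, [0.5, 0.6) bad, below 0.5 not useful. Bands are half-open
   with 0.9 inclusive, so 0.909 maps to "excellent" and 0.670 to
   "sufficient"; treating exactly 0.7 as "good" is this package's boundary
   convention.

A leakage canary is part of the test suite: perturbing held-out rows must
leave every training-fold artifact (NearMiss selection, standardization
constants) bit-for-bit unchanged. Training ROC-AUC can be pooled over
folds or averaged per fold; the search table reports the mean and
dispersion of the pooled per-run values.

## 6. Reliability and minimum sample size

Trial-retest reliability uses ICC(2,1) - two-way random effects, absolute
agreement, single measure - from the participants x trials ANOVA
decomposition, with the F-based confidence interval; form (2,1) matches
the design of repeated walks with no rater effect of interest.

The minimum sample size for developing a binary-outcome prediction model
follows the three standard criteria driven by an anticipated C-statistic
(0.8), outcome prevalence (0.2) and number of parameters (3):

1. expected uniform shrinkage >= 0.9:
   `n = p / ((S - 1) ln(1 - R2_CS / S))`;
2. apparent-to-adjusted R2 optimism <= 0.05, against the maximum attainable
   Cox-Snell R2 at the prevalence, `R2_max = 1 - (phi^phi (1-phi)^(1-phi))^2`;
3. overall risk estimated within +-0.05:
   `n = (z_0.975 / 0.05)^2 phi (1 - phi)`.

The C-statistic is converted to a Cox-Snell R2 under a binormal linear
predictor (class-conditional normal linear predictors, unit variance,
separation `sqrt(2) qnorm(C)`, event probabilities by Bayes' rule at the
prevalence) via a large Monte-Carlo draw - 2 million draws with fixed class
counts and antithetic variates, so the estimate is stable to ~1e-3 and
deterministic given the seed. At (C = 0.8, phi = 0.2, p = 3) this yields
R2_CS ~ 0.183, criterion minima of ~133-134, ~85 and 246, and a
recommended n (the maximum) of 246. The package prints every criterion
separately so that any single reported figure can be traced to the
criterion that produced it: a figure of ~134 corresponds to the shrinkage
criterion, while the three-criterion maximum is dominated by the
risk-precision criterion at this prevalence. No margin is tuned to force
one criterion to match another.

## 7. The synthetic gait generator

No real subject data ship with the package, so every pipeline stage is
validated against a parametric standing-start walk simulator with exact
ground truth (`simulate_walk`).

**Construction.** Strikes fall at `onset + k / cadence`, alternating feet,
left leading; each foot's swing lasts `swing_fraction x cycle`. Foot
trajectories are prescribed analytically: the stance foot is planted; the
swing ankle advances by a smoothstep and rises as `sin(pi u)`, so the
vertical ankle velocity attains its extremes exactly at toe-off and
touchdown - the events the detector defines. The spec of this module
sketched hip-angle-driven forward kinematics instead; that construction
cannot keep the stance foot planted while the pelvis advances, which the
contact-detection contract depends on, so the package prescribes feet and
places each knee on the hip-ankle perpendicular bisector at the height
that makes the internal hip-knee-ankle angle follow the programmed flexion
trajectory (baseline 8 degrees in stance plus a `knee_rom_amp` pulse in
swing). The programmed knee ROM is therefore recovered exactly by the
internal-angle recipe, at the price of a slightly elastic leg length -
acceptable for a test-pattern generator, and stated here rather than
hidden. The ankle's swing lift has a floor (5 cm plus 70% of the heel
lift): the shank swings through regardless of how little heel clearance a
walker keeps, and without that floor low-clearance walkers would carry
almost no detection signal, which is an artifact of the construction, not
of gait. Pelvis position is the mid-foot point; bob (at twice the stride
frequency), lateral sway, pelvic obliquity/rotation, trunk lean with a
hip-driven fore-aft rock, head sway and antiphase arm swing are sinusoids
gated by a walk envelope. Heel and toe heights are clipped at the floor
before i.i.d. Gaussian landmark noise (default 0.5% of stature, the
jitter scale of video pose engines) is added.

**Cohorts.** `simulate_cohort` draws per-participant parameters around the
defaults with realistic between-participant spreads, applies standardized
shifts `d` to fallers' parameters (defaults: knee ROM -0.8, heel lift
-0.8, swing fraction +0.5, trunk sway +0.5 - directions consistent with
the gait factors the fall-risk literature finds discriminative; the
magnitudes are synthetic test constructions and documented as such), and
adds between-trial jitter at 30% of the between-participant sd. The
default cohort shape is a training cohort of n = 190 at 12.1%
fall-history prevalence and a validation cohort of n = 28 at 25.0%,
roughly half men - the class-imbalance regime this kind of screening
study operates in. `simulate_feature_cohort` generates trial-by-feature
tables directly (participant means standard normal, faller shift `d` on
the informative features, within-participant noise sd 0.5) - the input
scale of the model pipeline, used to exercise screening and the
combination search against known ground truth without pose-level cost.

**What passing tests do and do not show.** The simulator has exact phase
structure, stationary parameters within a trial, isotropic Gaussian noise
and no occlusions, tracking failures, turning, or pose-engine bias. Tests
against it validate the *machinery* - segmentation accuracy, feature
recipes, normalization, selection and CV hygiene - not clinical validity
on real video. Headline discrimination figures from real cohorts depend
on subject data that do not ship with the package and are deliberately
not reproduction targets; on synthetic cohorts the end-to-end run
demonstrates, honestly, both genuine discrimination and the selection
instability expected with ~23 fallers among 77 candidate features.

## 8. Numerical choices and problem sizes

Filters: Butterworth order 4, zero-phase, demeaned and reflection-padded.
Event refinement: half-amplitude crossing with linear interpolation.
IRLS: tolerance 1e-8, max 100 iterations, ridge 1e-4 only on separation.
Bootstrap: 2000 stratified resamples, fixed seed, degenerate resamples
redrawn. Monte-Carlo C-to-R2 conversion: 2e6 draws, fixed class counts,
antithetic normals. Ties: mid-ranks in ROC-AUC (half credit), tied score
blocks as single thresholds in PR-AUC, row order in NearMiss, fewer
features then lexicographic in the search.

The test-suite problem sizes were chosen to exercise each property at
meaningful power on a single CPU: 20 parameter draws for segmentation
recovery, 20 cohort seeds (n = 190, prevalence 0.121, 10 candidates, 3
informative at d = 0.8) for the selection study, 6 CV runs per evaluation,
and 500 replicates for DeLong coverage. The analysis scripts run the full
study shape (190 + 28 participants, three trials each).

## 9. Known limitations

* The 77-entry catalogue is one concrete instantiation of its category
  structure; other recipe choices (swing-only ROMs, different plane
  assignments) are defensible and would change feature values.
* Contact detection assumes forward, roughly periodic standing-start gait;
  it is not built for turning, treadmill or stair walking, and it degrades
  for walkers with very low foot lift at slow cadence.
* The simulator is kinematic, not dynamic: no ground-reaction consistency,
  no balance control, and an elastic-leg knee construction.
* ICC values measured on simulated cohorts reflect the generator's
  variance components plus extraction noise; they say nothing about the
  reliability of any real acquisition setup.
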