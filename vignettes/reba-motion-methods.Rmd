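---
title: "Continuous REBA scoring from motion capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous REBA scoring from motion capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebamotion)
```

## The problem

Classical ballet training exposes professional dancers to sustained static
postures, repetitive movement, end-range joint positions and high landing
forces — the classic precursors of work-related musculoskeletal disorders.
The Rapid Entire Body Assessment (REBA) is the standard observational tool
for grading such exposure, but it was designed for an observer scoring a
single frozen posture. Inertial motion capture (a full-body suit sampling
joint angles at 240 Hz) makes it possible to score *every frame* of a
training session instead, and to summarise the result as the fraction of
working time spent in each risk band.

`rebamotion` implements that continuous pipeline: typed I/O for suit
exports, a frame-wise REBA engine, vertical load estimation from pelvic
kinematics, duration-normalised aggregation, a nonparametric comparison
battery, and a synthetic motion generator that makes the whole chain
testable without recorded human data.

## Frame-wise REBA

Each frame is scored through the published worksheet path:

* **Neck** from the C1-head joint: base 1 for forward tilt 0–20°, 2 beyond
  20° or in extension; +1 for rotation or lateral tilt beyond ±10°.
* **Trunk** from the *summed* flexion of the four instrumented spine joints
  (L5-S1, L4-L3, L1-T12, T1-C7): upright 1; ±0–20° 2; flexion 20–60° or
  extension beyond 20° 3; flexion beyond 60° 4; +1 for rotation/side-bend
  beyond ±10°.
* **Legs** from foot contacts and knee flexion: base 1 on two feet, 2
  otherwise; +1 per side for knee flexion 30–60°, +2 beyond 60°, worse side
  counts.
* **Load** from the magnitude of vertical pelvic acceleration: +1 beyond
  5 g, +2 beyond 10 g. Dancers carry no external weight, so the static
  weight bands of the worksheet are eliminated; take-off and landing
  accelerations take their place.
* **Arm chain** per side (shoulder elevation through the flexion and
  abduction planes, shoulder-girdle raise, elbow flexion, wrist
  flexion/rotation/deviation), composed through Table B with the worse side
  carried forward. The coupling score is fixed at 0 (nothing is held).
* **Tables A/B/C** are embedded transcriptions of the published worksheet,
  shipped as plain-text files and unit-tested for range, spot cells and
  monotonicity.
* **Activity**: over a trailing 10 s window, +1 if at least one scored
  joint group's flexion range is ≤ 7.5° (static hold), and +1 if the
  power-weighted mean frequency of the detrended summed flexion signal
  exceeds 5 Hz (rapid repeated change).

The final score is Table C + activity, on the 1–14 scale, banded as
1 = negligible, 2–3 low, 4–7 medium, 8–10 high, ≥ 11 very high.

### Design choices in the engine

Several points are underdetermined by the worksheet when it is applied
per-frame to continuous signals; the package fixes them explicitly:

* **Adjustment capping.** Rotation and side-bend adjustments are listed
  separately but the worksheet table domains (neck 1–3, trunk 1–5, wrist
  1–3) cannot absorb +2; each body part's twist adjustment is capped at +1.
* **Trunk neutral band.** "Upright" is a ±2° tolerance band
  (`reba_config(trunk = list(neutral_tol_deg = ...))`): an exact-zero band
  never fires on real signals.
* **Flight frames.** The worksheet does not define a leg base score with no
  support at all; flight uses base 2 ("one leg raised" — maximally unstable
  support).
* **Arm side combination.** The legs rule (score both sides, take the
  worse) is extended to the arm chain: Table B is computed per side and the
  worse side becomes Score B. Worst-case scoring is standard observational
  practice.
* **Abducted arms.** The worksheet prints elevation bands for flexion only;
  abduction is mapped through the same bands and the worse plane counts,
  since elevation in any plane is the construct being scored.
* **Neutral-stance static hold.** A static hold formally satisfies the
  activity criterion even in a fully neutral stance, which would put quiet
  standing at score 2. The engine applies the static increment only on
  frames whose postural score (Table C) exceeds 1: a neutral stance held
  still is not a static *working* posture. This pins the scale floor —
  all-neutral standing scores exactly 1 — while held working postures still
  receive the increment. `score_activity()` itself always reports the raw
  flags.
* **Spectral flag.** "Mean power frequency above 5" is read as Hz, computed
  by periodogram on the detrended summed flexion signal over the trailing
  window. Two numerical guards apply: the flag requires a detrended RMS
  above 5° (white sensor noise alone, at the generator's 0.5° per channel,
  has a summed RMS near 1.8° and a mean power frequency near a quarter of
  the sampling rate, so an amplitude gate is essential); and in
  `compute_reba_series()` the spectral flag is evaluated every 0.25 s and
  held between evaluation points. `score_activity()` at a single frame is
  exact.

## Load estimation

Vertical ground reaction force is estimated from the pelvic centre alone:
the acceleration is the central second difference of the vertical pelvis
position (exact for the parabolic arcs of ballistic flight), and the
supported load in body-weight units is

$$ \mathrm{load} = \max\!\left(0,\; 1 + \ddot z / g\right), $$

so quiet standing carries 1 BW, ballistic flight exactly 0 BW, and landings
more than 1 BW. The gravity offset is required to reproduce both anchors; a
raw second derivative alone would put standing at 0. Differentiation is
unsmoothed by default (no filter is assumed); an optional zero-phase
Butterworth low-pass is available and, as with any smoothing before
differencing, it systematically *underestimates* sharp landing peaks.

Loads are binned in 0.5 BW graduations from 0 to 5 BW (nearest centre, ties
upward, values beyond the last edge clamped into the 5.0 bin — the binning
rule is fixed for determinism), and the mean load is taken from the binned
distribution.

## The training plan

The built-in plan is a condensed 80-minute professional class: barre
(phase 1), centre (phase 2) and jumps/allegro (phase 3), with per-row cycle
counts, execution multipliers and block durations. Pointe rows belong to
the female programme only and the closing manege jump row to the male
programme; the pure load durations total 1358 s (male, 16 measurements) and
1410 s (female, 19 measurements). One centre row is printed in the source
schedule as a right-and-left 72 s pair, but the totals are only consistent
with the block counted once; the plan follows the totals and documents the
discrepancy. Likewise the printed manege row ("10 s × 3") is expanded into
three 10 s measurements (demi-pointe right, demi-pointe left, pointe
right), which is what reconciles the 19/16 measurement counts.

## The synthetic generator

The generator scripts each plan row as a stylised kinematic sketch: posture
set-points with raised-cosine keyframe transitions, sinusoidal joint
oscillations (gated off during held balances), continuous unwrapped spins
for pirouettes, and jump programs whose pelvis trajectory is piecewise
closed-form — raised-cosine push-off and landing acceleration transients
joined to an *exact* parabola during flight, with foot contacts false
exactly during flight. Phase-3 programs aim at 20% of the sequence airborne;
landing transients peak between 1.8 and 2.6 g by row. Independent Gaussian
noise (default σ = 0.5° per channel, well under the ±2° accuracy of
suit-based capture) is added to the angles; the pelvis trajectory is left
noiseless because position noise of even 1 mm would dominate a 240 Hz
second derivative, which is a property of the estimator, not of the
generator. The default head carriage is 8° of forward gaze: a 0° set-point
would sit exactly on the printed neck band edge and angle noise would then
flip the base score on half the frames — a degenerate fixture rather than a
meaningful condition.

Ground truth is the noiseless evaluation of the same engine, plus the
intended flight mask and load series; property tests assert that noiseless
recordings reproduce their ground truth exactly and that interior flight
frames score exactly 0 BW through the estimator.

What the generator does *not* emulate: biomechanically valid choreography,
inter-joint coupling, soft-tissue artefact, sensor drift, or gap-filled
real exports. Passing tests therefore demonstrate the correctness of the
scoring, aggregation and statistics given angle-level inputs — not the
fidelity of any particular suit.

### Scripted group effects

Gender (or any group) effects are injected as posture offsets with a known
truth: for subject-level summaries distributed normally with common SD, the
implied Cliff's delta is `2 * pnorm(offset / (sd * sqrt(2))) - 1`
(`delta_from_offset()`), so an offset can be tuned to a target effect size
and the recovered delta checked against it. Per-subject habitual-posture
offsets are drawn from N(0, 2°).

## Statistics

The unit of analysis for between-group tests is the per-subject
duration-weighted summary (one observation per subject): the reported group
sizes in studies of this design correspond to subjects, and frame-level
testing would inflate n by four orders of magnitude. The battery is:
Wilcoxon–Mann–Whitney for two groups (tie-corrected, continuity-corrected
normal-approximation z, negative when the first group — male, by pipeline
convention — is stochastically smaller; exact U tail via the
dynamic-programming distribution for tie-free samples with
n₁·n₂ ≤ 400), Kruskal–Wallis for three or more, a Dunn-type pairwise
mean-rank follow-up with Bonferroni-adjusted simultaneous normal
confidence limits (the follow-up method is an approximation of the
package's own choosing), Bonferroni–Holm step-down correction within each
comparison family (strictest threshold α/m, e.g. 0.05/12 ≈ 0.0042 for the
12-score detailed family), and Cliff's delta with bands |δ| < 0.33 small,
0.33–0.5 medium, > 0.5 large (boundary values are assigned to the closure
of the lower band, since the printed strict inequalities leave them
unassigned). A one-sample Kolmogorov–Smirnov normality gate is computed and
reported, but the battery stays nonparametric regardless of its outcome.

## Problem sizes and calibration

The suite's statistical calibration runs at two levels, by design:

* **Subject level** (1000 replicates): under identical settings for both
  groups, per-subject summaries are drawn from the generator's
  subject-effect model at study size (16 + 12) and the MWU rejection rate
  at α = 0.05 is required to sit in 0.05 ± 0.02; the direction of a large
  injected effect must be recovered in ≥ 99% of replicates.
* **Pipeline level** (100 replicates): full two-gender micro-studies
  (compressed durations, reduced sampling rate) run end-to-end through
  `generate_study()` → `run_session()`, and the overall gender comparison
  must be non-significant in ≥ 90% of null replicates.

Full-scale sessions (240 Hz, printed durations) are exercised once in the
flight-fraction and anchor tests; aggregate tests use compressed durations
(`time_scale`) and reduced rates, which the generator supports as
first-class parameters precisely so that statistical behaviour can be
studied at many replicates.

## Known limitations

* Pelvis-only load estimation ignores force partitioning between limbs and
  underestimates landing peaks if smoothing is enabled; it is not a
  force-plate substitute.
* Input angles are assumed already decomposed into
  flexion/abduction/rotation; no Euler-order conversion is attempted.
* The REBA risk bands are derived from industrial work; nothing in the
  package validates them as predictors of dance injury.
* The activity score's spectral criterion is a documented interpretation
  (Hz, summed flexion signal); the original adaptation does not state its
  units or signal.
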