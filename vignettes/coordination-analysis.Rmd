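---
title: "Continuous relative phase, MARP and DP: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous relative phase, MARP and DP: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpcoord)
```

## The problem

During backward locomotion — a staple of handball defence — an athlete cannot
see the path of travel and must rely on proprioception to coordinate the
lower limb. A standard dynamical-systems way to quantify that coordination is
the **continuous relative phase (CRP)** between adjacent joints (ankle–knee,
knee–pelvis): the instantaneous difference between the joints' phase angles
over a movement cycle. Two summary indices are then compared across groups
and training stages:

* **MARP** (mean absolute relative phase) — the mean of |CRP| over the cycle.
  Low values mean the joints move in phase; high values mean out-of-phase,
  more differentiated coordination, typical of skilled performers.
* **DP** (deviation phase) — the mean over the cycle of the across-cycle
  standard deviation of CRP. Low values mean stable, reproducible
  coordination; high values mean a more variable (or more flexible)
  organisation.

This package implements the full chain — phase portraits, CRP, MARP/DP,
group statistics — plus a synthetic cohort generator with analytic ground
truth, so that every stage can be verified without access to motion-capture
data.

## From joint angle to phase angle

For each joint the angle series $x(t)$ (degrees, sagittal plane, relative to
the joint's neutral position) is differentiated with central differences
(two-point one-sided at the ends), and the pair is **amplitude-normalized**:

$$x_{\mathrm{norm}} = \frac{2(x - \min x)}{\max x - \min x} - 1,\qquad
  v_{\mathrm{norm}} = \frac{\dot x}{\max|\dot x|}.$$

The angle is mapped onto $[-1, 1]$ by its range; the velocity is divided by
its maximum magnitude so that it keeps its sign and, crucially, its zero.
A min–max rescale of velocity would shift the phase-plane origin and bias
every phase angle; preserving the zero keeps "zero velocity" on the
$x$-axis of the portrait.

The **phase angle** is the four-quadrant polar angle of the portrait point,
$\phi = \mathrm{atan2}(v_{\mathrm{norm}}, x_{\mathrm{norm}})$, converted to
degrees and unwrapped so adjacent samples never jump by 180° or more. With
this convention $(1, 0) \mapsto 0°$ and $(0, 1) \mapsto 90°$, and a harmonic
oscillation traverses the portrait clockwise, so $\phi$ decreases by 360° per
cycle. This is a pure convention; CRP differences are unaffected by its
orientation.

## Two routes to CRP, and their agreement

CRP for a coupling is $\theta = \phi_{\mathrm{distal}} -
\phi_{\mathrm{proximal}}$. The package also implements the single-formula
route

$$\theta_i = \mathrm{atan2}\!\left(\dot x_{1}x_{2} - \dot x_{2}x_{1},\;
   x_{1}x_{2} + \dot x_{1}\dot x_{2}\right)$$

(all terms amplitude-normalized; joint 1 distal), which is algebraically the
same polar-angle difference. The two routes agree to machine precision on
narrowband signals, and that agreement is used throughout the test suite as
a two-route oracle. Two numerical details matter:

* **Denominator sign.** The plus sign between the $x_1 x_2$ and
  $\dot x_1 \dot x_2$ terms is required: with a minus sign the formula does
  not return $\theta \equiv 0$ for identical signals, violating the defining
  property that zero CRP means perfectly in-phase joints. A minus-sign
  variant circulating in some write-ups is available behind
  `denominator = "printed"` for auditing, and the test suite demonstrates it
  fails the in-phase identity.
* **Branch alignment.** Both routes shift the unwrapped $\theta$ by a
  multiple of 360° so the first sample lies in $(-180°, 180°]$. Without
  this, the two routes can legitimately disagree by 360° for couplings near
  anti-phase.

Under these conventions a **positive** CRP means the distal joint sits at an
earlier point of its own cycle than the proximal joint (the distal joint
lags in time). Where the CRP slope is positive, the distal phase angle is
advancing faster than the proximal one.

## Time normalization and the indices

Each trial is treated as one movement cycle. The CRP series is resampled by
linear interpolation onto a uniform 0–100% grid of $N = 101$ points — the
long-standing convention for gait-cycle ensembles; $N$ is configurable
(`n_cycle_points`, minimum 11). Linear interpolation keeps the first and
last samples fixed, is exact for linear segments, and for signals sampled at
≥ 100 points per cycle its error is far below every tolerance used here
(measured < $10^{-3}$ for band-limited sinusoids in the tests).

$$\mathrm{MARP} = \frac{1}{N}\sum_{i=1}^{N} |\theta_i|, \qquad
  \mathrm{DP} = \frac{1}{N}\sum_{i=1}^{N} \mathrm{SD}_i,$$

where $\mathrm{SD}_i$ is the sample standard deviation (denominator $n-1$)
of $\theta_i$ across replicate curves. The absolute value in MARP is what
makes the index symmetric in which joint leads — without it, a formulation
summing signed $\theta_i$ can report 0 for strongly coupled joints that
alternate lead; that signed variant is available via `marp(..., absolute =
FALSE)` for auditing only. The sample (not population) SD matches the
small-sample inferential use downstream.

**Aggregation hierarchy.** Per-trial CRP curves → per-subject MARP (mean of
per-trial MARPs) and per-subject DP (pointwise SD across that subject's
trials, averaged over the cycle) → group mean (SD). One scalar per subject
is what makes the downstream t-tests and ANOVAs well-formed (a two-group
comparison of 7 + 7 subjects has 12 degrees of freedom). DP for a subject
with a single trial is reported as missing, never zero: one cycle carries no
variability information, and zero would fake perfect stability. The ensemble
layer (`ensemble_curve`, pointwise mean ± SD across curves of a whole
group) is exposed separately for visualisation; the subject layer feeds the
statistics.

**Degenerate inputs.** A constant angle series (frozen joint) or an
identically zero velocity has no defined phase; these error out rather than
silently returning zeros. A phase-plane point exactly at the origin is
likewise an error identifying the sample.

## The synthetic cohort

The generator emulates a three-group training study: 7 control novices and
7 test novices measured pre and post a six-week balance programme, and 14
professionals measured once as a reference (28 subjects; demographics in the
manifest use round values near 21 y, 1.7 m, 74 kg). Each joint follows a
single-harmonic cycle, $A\sin(2\pi t/T) + c$ with $A = 30°$, $c = 10°$,
$T = 0.6$ s, 200 samples per cycle, and each coupling's distal joint is
delayed by a controlled phase offset, so the CRP of the coupling **equals
that offset by construction**. Three noise layers:

* between-subject: subject offsets $\sim N(\Delta_{\mathrm{group,stage}},
  \sigma_b)$;
* within-subject: each trial shifts every coupling offset by a constant
  $\sim N(0, \sigma_w)$ — a *constant* per-trial phase shift, so the
  expected DP has the closed form $c_4(K)\,\sigma_w$ for $K$ trials, with
  $c_4$ the standard small-sample correction
  $E[s]/\sigma = \sqrt{2/(K{-}1)}\;\Gamma(K/2)/\Gamma((K{-}1)/2)$;
* optional additive per-sample angle noise (default 0 — per-sample noise
  also perturbs the phase and is deliberately excluded from the closed-form
  ground truth; turn it on to stress-test, not to calibrate).

Expected per-subject MARP is the folded-normal mean of
$|N(\Delta, \sigma_b)|$, which is $|\Delta|$ for offsets large relative to
$\sigma_b$.

The `study_preset()` encodes the study conditions in degrees: both novice
groups share one true baseline offset (17° ankle–knee, 24° knee–pelvis) —
randomized groups are equal in truth at baseline, and observed baseline
differences are sampling noise — professionals sit at 38°/34°, and training
shifts novices to 32°/28°. Between-subject SDs (5–21°) and jitter SDs
(0.15–0.3°) scale the relative magnitudes typical of published MARP/DP
tables (MARP SD about a third of the mean; DP about a hundredth of MARP).
Ten trials per subject and stage is a realistic laboratory session count.
Pre and post subject offsets are drawn independently — the training response
is modelled as a stage-dependent shift with no baseline correlation, which
is a stated simplification, not an estimate.

What the generator does **not** emulate: multi-harmonic gait waveforms,
event detection and cycle segmentation, soft-tissue/marker artefact,
filtering, inter-joint amplitude asymmetries, or any learning dynamics.
Passing tests therefore validate the *estimators* (CRP, MARP, DP, and the
inference chain) under controlled truth; they do not certify behaviour on
raw motion-capture data, which needs upstream segmentation and filtering
this package deliberately leaves out of scope.

## The statistical workflow

All inference runs on per-subject scalars, two-sided, at $\alpha = 0.05$ by
default:

1. **Assumption gate**: Shapiro–Wilk per group and Levene's test (centred
   on the mean) across groups. A failed gate is recorded and warned about,
   and the parametric analysis continues — the workflow mirrors studies
   that report the gate and proceed parametrically; the report keeps the
   gate output so a reader can judge.
2. **Baseline**: pooled-variance independent t between the novice groups
   (df $= n_1{+}n_2{-}2$), and a one-way ANOVA over the three groups with
   $\eta^2 = SS_b/SS_t$.
3. **Post hoc**: unadjusted pairwise pooled t-tests, each with its own df
   (7/7/14 gives the 12/19/19 pattern). Unadjusted is the default because it
   reproduces the df/p structure of typical published tables; Bonferroni is
   one switch away (`posthoc_correction = "bonferroni"`).
4. **Training effect**: paired t on pre/post within each novice group
   (df $= n{-}1$, effect size $d_z$), then the post-training t-test and
   ANOVA.

The pooled t, paired t, and ANOVA are computed from closed-form
summary-statistic formulas — the same engine powers `summary_stat_t()`, the
audit tool that reproduces a published t-test from printed group means and
SDs alone — and are cross-checked in the test suite against the reference
implementations in base R (`t.test`, `aov`) to $10^{-8}$ on random
instances. Welch's correction is available per test or automatically on
Levene failure (`variance_policy = "auto_levene"`). Cohen's d always uses
the pooled SD. Zero-variance cells are flagged (t reported as 0 for equal
means, infinite otherwise) rather than producing NaN.

## Problem sizes and numerical tolerances

The test and acceptance workloads use: 500-sample single-cycle sinusoids for
analytic recovery (route agreement $< 10^{-6}$°, MARP within 1° of the true
offset — the 1° budget absorbs amplitude-normalization distortion of
finitely sampled sinusoids); 60 seeded subjects of 10 cycles for the DP
calibration (within 10% of $c_4\sigma_w$); 20 seeded replicates of the full
7/7/14 cohort for recovery of group means (within 2 standard errors of the
seed-averaged mean) and for the baseline inference pattern (professionals
separated from both novice groups, novices not separated, in ≥ 90% of
replicates); and 2000 null replicates for the type-I error of the t engine
(5% ± 1.5%).

## Known limitations

* One trial = one pre-segmented cycle; no event detection or multi-cycle
  splitting.
* CRP is computed from amplitude-normalized portraits only; a
  Hilbert-transform phase is not provided.
* The angular unit of published MARP/DP tables in this literature is not
  always stated; the package reports degrees (radians by config) and makes
  no unit claim for any external table.
* No repeated-measures or mixed-effects models; the workflow is the exact
  t/ANOVA chain described above.
* The pre/post independence simplification above means simulated paired
  tests are conservative relative to a cohort with strong baseline
  correlation.
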