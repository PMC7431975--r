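---
title: "Silent ihMT ratio mapping and repeatability analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silent ihMT ratio mapping and repeatability analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihmtr)
```

## The measurement

Inhomogeneous magnetization transfer (ihMT) exploits the dipolar order of
myelin lipids: saturating the bound proton pool with a single off-resonance
frequency (+ or −) and with a dual, alternating (±) scheme produces different
signal attenuation, and the difference is close to zero everywhere in the
head except myelinated tissue. One scan of a silent zero-echo-time (RUFIS)
ihMT protocol yields six co-registered volumes — the unsaturated reference
`S0`, single-sided `S+` and `S−`, dual-sided `S+/−` and `S−/+`, and a
T1-prepared volume `ST1` — from which five semi-quantitative ratios are
computed voxelwise:

* `MTR  = 1 − (S+ + S−) / (2 S0)`
* `eMTR = 1 − (S+/− + S−/+) / (2 S0)`
* `MTasym = (S+ − S−) / S0`
* `ihMTR = 2 (eMTR − MTR)`
* `ihMTRinv = 2 ST1 (1/S+/− + 1/S−/+ − 1/S+ − 1/S−)`

All five are ratios of signals acquired with identical receive gain, so they
are invariant under a global rescaling of the six volumes; `compute_ratio_maps()`
preserves this exactly. The inverse ratio trades the simple difference for a
reciprocal form scaled by the T1-prepared signal, which damps T1 and
transmit-field (B1) confounds at the cost of sensitivity to low-signal
voxels — hence its stricter mask.

### Masking and division guards

Published ratio maps are visibly brain-masked, but how the background was
excluded is rarely stated. We keep voxels with `S0 > 0.05 × max(S0)` by
default; an explicit mask volume overrides the threshold. Any voxel with a
non-positive denominator becomes `NaN` rather than being clipped, so
downstream ROI statistics can drop it explicitly, and negative ratio values
(real in CSF for ihMTR) are never clipped. `NaN` is the single mask value
throughout the package.

## Protocol arithmetic

`protocol_timing()` encodes the silent sequence's printed parameters
(TR 1.764 ms, 32 spokes per segment, 10 saturation pulses of 0.5 ms with
0.5 ms gaps, 8.75 µT pulse B1rms, 48 dummy segments, 65 s per volume, five
volumes). Ramp/switching overheads are not printed in protocol descriptions,
so they are explicit parameters whose defaults are back-computed from the
stated totals (segment overhead `68.6 − 32×1.764 = 12.152` ms; preparation
overhead `0.8` ms). Dummy segments are costed at the segment time only —
`48 × 68.6 ms ≈ 3.3 s`, which is consistent with the stated preamble,
whereas including a preparation block between dummies would not be. The
per-volume scan time is taken to exclude the dummy preamble, since
`5 × (65 + 3.29) s` reproduces the stated total of 5 min 41 s and including
it would not. The module B1rms is the pulse B1rms scaled by the square root
of the train duty cycle (`√0.5`), using the nominal pulses-plus-gaps window;
it is returned exact and displayed to 0.1 µT.

## The synthetic study

Every statistical claim in the package is validated against a generator
whose structure matches the analysis assumptions, not against acquired
data. `phantom_spec()` fixes the study conditions:

* **Geometry** — a 64³ ellipsoidal head (3 mm voxels): GM shell, WM core,
  two CSF ventricles, and ten ROI boxes carved into the WM core (labels
  11–20), standing in for bilateral white-matter tract ROIs.
* **Tissue truths** — WM `mtr = 0.20`, `emtr = 0.26`, `mtasym = 0.01`,
  `t1_factor = 0.37`, giving `ihMTR = 0.12` and `ihMTRinv ≈ 0.15`: the scale
  reported for healthy WM at 3 T. GM values are lower; CSF has `emtr`
  slightly below `mtr`, so its ihMTR is slightly negative, as observed in
  vivo. Each ROI carries a small deterministic eMTR offset
  (±0.009 spread) so ROI is a genuine factor.
* **Design** — 12 subjects × 2 sessions × 2 repeats. Subject and scan
  effects are additive on eMTR with SDs 0.005 and 0.004; on the ihMTR scale
  (factor 2) these give a between-subject CoV near 8–10 % of the WM value
  and an ICC in the moderate band, echoing reported repeatability.
* **Head orientation** — one angle per session from a normal (mean 7°,
  SD 5°) truncated at zero, matching the reported median of about 7°; WM
  eMTR decreases by `angle_slope = 0.001` per degree. The sign and
  session-level sharing mirror the observed orientation confound; the
  magnitude is this package's choice of a "small but detectable" effect
  (about −0.27 % of ihMTRinv per degree). Whether orientation acts on the
  single- or dual-saturation signals is not identifiable from ratio data;
  implementing it through eMTR is a modelling choice, and it propagates to
  both ihMT metrics.
* **Noise** — Rician (`sqrt((x+n1)² + n2²)`), SD 1 a.u. against `S0 = 100`.
  At this SNR the Rician bias of the ratio estimates is negligible.
* **Transforms** — each scan's native→atlas transform is emitted as the
  rotation by −angle about the x axis, so `head_angle()` recovers the
  generator's angle exactly; rotating the image grid itself would only
  exercise the (out-of-scope) registration step.
* **Seeding** — one master seed; every random draw uses a stream derived
  from fixed per-subject/session/repeat offsets, so identical specs are
  bit-reproducible and adding subjects never reshuffles existing scans.

`simulate_study()` renders volumes; `simulate_roi_study()` generates the
same design directly at the ROI-mean level (residual SD 0.002 on eMTR,
emulating what voxel noise averages down to over an ROI box), which is what
replicate-study simulations use — estimating type-I error over 200 studies
does not require rendering 9,600 volumes. `simulate_icc_study()` draws the
bare two-way model `y_ij = µ + s_i + r_j + e_ij` for ICC calibration
studies.

What the generator does **not** emulate: realistic anatomy and partial
volume, B0/B1 field structure, motion between the six volumes, registration
error, and orientation dependence at the fibre (rather than whole-head)
level. Passing tests therefore demonstrate correctness of the arithmetic
and the statistical machinery under the stated model, not robustness to
those real-data effects.

## Reliability: regularized ICC(2,1)

ROI means from the four scans per subject enter a two-way random-effects
model (subjects and scans random; session and repeat are flattened into a
single 4-level scan factor). `fit_two_way_random()` maximizes the REML
log-likelihood plus a gamma log-density (default shape 2, rate 0.5)
evaluated at the subject and scan standard deviations; the residual SD is
unpenalized. The gamma density vanishes at zero, so the penalty keeps SD
estimates off the boundary — on small samples unpenalized REML returns
exactly zero subject variance in a substantial fraction of null-ish
datasets, and the penalized fit essentially never does, while large-sample
estimates agree with ANOVA method-of-moments to within a few percent.

Numerical choices: optimization is over log-SDs (unconstrained), by
Nelder-Mead from method-of-moments starting values floored at a small
positive value, relative tolerance 1e-10 — deterministic, so identical data
give identical estimates. Complete designs use the closed-form balanced
REML likelihood (the three ANOVA sums of squares are sufficient statistics);
incomplete designs fall back to a dense-matrix REML, and more than 20 %
missing cells is an error rather than a silent fit.

`icc21()` is `σ²_subject / (σ²_subject + σ²_scan + σ²_resid)`; `0/0` is
reported missing. Confidence intervals are bootstrap percentile intervals
(2.5/97.5 after refitting on each replicate). The resampling unit is a
design choice that usually goes unstated; we evaluated both candidates by
simulation at a 12-subject, 4-scan design with true ICC 0.7. Resampling
subjects with replacement understates the between-subject variance of the
replicates when there are only a dozen subjects, and its nominal-95 %
interval covered the truth in only about two thirds of studies, almost
always missing from below. The default is therefore a **parametric**
bootstrap — whole studies simulated from the fitted variance components —
whose coverage in the same simulation sits close to nominal (about
91–93 %); subject resampling
remains available as `type = "subject"`. Categories: poor < 0.5 ≤ moderate
< 0.75 ≤ good < 0.9 ≤ excellent, with boundary values assigned upward.

Two caveats are worth stating. The prior is placed on the SD scale — the
common reading of "gamma prior on variance components" in the regularized
mixed-model tradition, and the default of the software that popularized it;
a variance-scale prior is a one-line change but is not exposed. And because
the prior has units, the regularized ICC is *not* invariant under rescaling
the data (the unpenalized REML ICC is, to optimizer precision); analyses
should keep metrics on one scale, and the package stores fractions
throughout.

## Head orientation

The angle between the scan's head-foot axis and the atlas Z axis is
extracted from the concatenated affine chain: apply the linear part to
`Z = (0,0,1)`, normalize (affine chains may carry scale, and without
normalization the arccos argument would not be a cosine), and take the
arccos of the dot product with Z. The angle is unsigned — a forward and a
backward tilt of equal size are indistinguishable — and translation is
ignored.

The angle effect on an ihMT metric is estimated with a linear mixed model
on the ROI means: `value ~ angle + ROI + angle:ROI + subject` (fixed) with
random intercepts for subject, subject:ROI, **and scan**. The per-scan
intercept is this package's addition: the ten ROI values of one scan share
acquisition-level noise, and without a scan-level term a session-level
covariate like head angle is tested against roughly ten times too many
effective degrees of freedom — in simulation the nominal 5 % test rejected
true nulls 45 % of the time, versus 2–7 % with the term included. ROI and
subject use sum-to-zero contrasts, so the angle coefficient is the average
within-subject slope. F-tests use Satterthwaite denominator degrees of
freedom (a simpler, asymptotically close alternative to Kenward-Roger),
and `method = "bootstrap"` provides a parametric-bootstrap p-value as a
cross-check. If every subject has a single distinct angle the slope is
aliased with the subject fixed effects and the fit is refused with an
explanatory error.

## Coefficients of variation

`cov_between()` pools all scans and subjects (sample SD over mean);
`cov_within()` computes each subject's SD/mean over its scans and averages
subjects without weighting. The n−1 SD is used throughout (the convention
is rarely stated; the choice is immaterial to the within/between ordering).
Voxelwise maps (`cov_map()`) apply the same definitions per voxel and
propagate `NaN`. With positive subject variance the within-subject CoV
falls below the between-subject CoV in expectation, which the simulated
studies reproduce.

## Problem sizes used in validation

The shipped validation suite uses the full 64³ phantom for the exact
round-trip check, table-level replicate studies (12 subjects × 4 scans) for
the statistical calibrations — 50 replicates per ICC level, 200 studies ×
200 resamples for bootstrap coverage, 200 null and 100 alternative studies
for the angle model — and 32³ two-subject studies for end-to-end plumbing.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the suite quick to run.

## Known limitations

* Registration, motion correction and nonlinear warps are consumed, never
  estimated; transform files are plain-text 4×4 affines.
* No quantitative ihMT modelling (bound-pool fractions, dipolar relaxation
  times) and no B1 mapping or correction.
* The angle analysis cannot distinguish rotation direction and does not
  control for within-ROI fibre orientation.
* The regularized ICC depends on the measurement scale through the prior
  (see above).
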