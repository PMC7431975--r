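# ihmtr

Inhomogeneous magnetization transfer (ihMT) is an MRI contrast that is
selectively sensitive to the dipolar order of myelin lipids: saturating the
bound proton pool at a single off-resonance frequency attenuates the signal
differently than alternating dual-sided (±) saturation, and the difference
is near zero everywhere in the head except myelinated tissue. `ihmtr`
implements the analysis pipeline for a silent (zero-echo-time, RUFIS) ihMT
protocol, from the six weighted volumes of one scan to the repeatability and
head-orientation statistics of a multi-session study:

* **Ratio maps** — voxelwise `MTR = 1 − (S⁺ + S⁻)/(2 S₀)`,
  `eMTR = 1 − (S⁺ᐟ⁻ + S⁻ᐟ⁺)/(2 S₀)`, `MTasym = (S⁺ − S⁻)/S₀`,
  `ihMTR = 2 (eMTR − MTR)` and
  `ihMTRinv = 2 S_T1 (1/S⁺ᐟ⁻ + 1/S⁻ᐟ⁺ − 1/S⁺ − 1/S⁻)`,
  with S₀-threshold or explicit masking, NaN division guards, and NIfTI-1
  I/O throughout.
* **ROI statistics** — atlas labels pulled into native space by
  nearest-neighbour resampling through concatenated affine chains; per-ROI
  means; between-subject and average within-subject coefficients of
  variation, both as tables and as voxelwise maps.
* **Repeatability** — ICC(2,1) from a two-way random-effects model
  (subjects × scans) fitted by REML with a weakly informative gamma prior
  (shape 2, rate 0.5) on the random-effect standard deviations, which keeps
  small-sample variance estimates off the zero boundary; bootstrap
  percentile confidence intervals; poor/moderate/good/excellent
  classification at 0.5/0.75/0.9.
* **Head orientation** — rotation angle of the head-foot axis extracted
  from native→atlas affine chains, and a linear mixed model
  (lme4/lmerTest, Satterthwaite F) for the angle effect on inverse ihMTR
  across ROIs.
* **Synthetic studies** — a digital head phantom whose six weighted volumes
  are synthesized by inverting the ratio definitions from tissue-wise
  ground truth, with subject/scan variance components, per-session head
  rotation with a linear angle effect, Rician noise, and ground-truth
  transforms; plus fast table-level generators for replicate-study
  simulations.
* **Protocol arithmetic** — deterministic timing and saturation-power
  figures (segment time, preparation time, dummy preamble, total duration,
  module B1rms) for the silent sequence.

## Worked example

```r
library(ihmtr)

## a complete synthetic study: 12 subjects x 2 sessions x 2 repeats
spec  <- phantom_spec(seed = 42)
study <- simulate_study(spec)          # volumes + transforms + truth
maps  <- compute_ratio_maps(study$scans[[1]]$volumes)
print(maps)
#> ratio_maps: 64 x 64 x 64 voxels; 81104 voxels in mask

## ROI analysis at the table level (no volumes needed for statistics)
rs  <- simulate_roi_study(spec)
rel <- icc_reliability(rs$table, metric = "ihmtr_inv", n_boot = 200, seed = 1)
head(rel[, c("roi", "icc", "ci_low", "ci_high", "category")], 3)
#>     roi       icc    ci_low   ci_high category
#> 1 roi01 0.3469400 0.1057742 0.6217195     poor
#> 2 roi02 0.4279332 0.1465698 0.6428169     poor
#> 3 roi03 0.3730434 0.1201550 0.6386357     poor
```

The ICC column is σ²_subject / (σ²_subject + σ²_scan + σ²_resid) from the
regularized fit; the interval is a parametric-bootstrap 95 % percentile
interval.

```r
## head-orientation analysis
fit <- fit_angle_model(rs$table, rs$angles, metric = "ihmtr_inv")
print(fit)
#> angle effect: slope -0.003727 per degree, F(1, 35.0) = 43.45, p = 1.29e-07
#> angle x ROI:  F(9, 414.0) = 1.51, p = 0.144

## protocol arithmetic
p <- protocol_timing()
print(p)
#> protocol_timing: segment 68.6 ms | prep 10.8 ms | dummies 3.3 s | total 5 minutes 41 seconds | module B1rms 6.2 uT
```

The negative slope says inverse ihMTR decreases as the head tilts away from
the scanner's Z axis — about −0.37 % of signal fraction per degree in this
synthetic study — with the angle-by-ROI interaction consistent with a
homogeneous effect across ROIs. In this run the ICCs land in the poor band:
the per-session head rotation feeds session-level variance into the scan
component, degrading repeatability exactly the way a real orientation
confound would.

A thin command-line front end over the same functions is in
`inst/scripts/ihmt.R` (`timing`, `maps`, `simulate`, `roi`, `cov`, `icc`,
`angle`, `angle-model` subcommands).

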