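---
title: "Intrinsic neural timescales: estimator, synthetic cohorts, and inference conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic neural timescales: estimator, synthetic cohorts, and inference conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intpipe)
```

## The INT index

For a voxel time series \(x_1,\dots,x_T\) sampled every TR seconds, the
sample autocorrelation at lag \(k\) is the conventional biased estimator

\[
\hat\rho(k) \;=\; \frac{\tfrac1T\sum_{t=1}^{T-k}(x_t-\bar x)(x_{t+k}-\bar x)}
                      {\tfrac1T\sum_{t=1}^{T}(x_t-\bar x)^2},
\]

and the intrinsic neural timescale is

\[
\widehat{\mathrm{INT}} \;=\; \mathrm{TR}\sum_{k=1}^{m-1}\hat\rho(k),
\qquad m=\min\{k\ge 1: \hat\rho(k)<0\}.
\]

Under an AR(1) process with coefficient \(\phi\), \(\rho(k)=\phi^k\) and
the population value is \(\mathrm{TR}\,\phi/(1-\phi)\), which is the
ground truth used throughout the tests.

Conventions that the description above leaves open, and how this package
fixes them:

* **Lag 0 is excluded by default.** Published ROI means below one TR
  (0.5–1.0 s at TR = 2 s) are arithmetically impossible if the lag-0
  value (\(\equiv 1\), contributing TR seconds) were included, so the sum
  starts at lag 1. `include_lag0 = TRUE` is exposed for sensitivity
  analysis only.
* **Strictly negative stops the scan.** An ACF value of exactly zero is
  included (contributing nothing) and scanning continues; "became
  negative" is read literally. This matters only on degenerate inputs.
* **ACF estimator.** The biased (1/T) denominator with mean removal. It
  guarantees a valid (positive semi-definite) autocorrelation sequence;
  the unbiased variant can exceed 1 in magnitude at large lags.
* **Maximum lag** defaults to half the session length. If no negative
  value occurs before it (essentially impossible for fMRI-like data), all
  computed lags are summed and a truncation warning is raised.
* **Multi-session series are never concatenated.** The INT is computed
  per session and averaged. Concatenation would inject a spurious
  discontinuity into the ACF at the session boundary; averaging keeps the
  estimator unbiased at the cost of using each session's shorter T. Two
  identical sessions reproduce the single-session value exactly, which
  the tests assert.
* **Degenerate (constant) voxels** get INT = 0 and are counted in a
  message rather than aborting a whole-brain run; whole-mask degeneracy
  is the caller's error.

## The synthetic cohort: a stated world

`simulate_cohort` generates everything the downstream analysis consumes,
with known truth. Its choices, and why:

* **AR(1) voxels.** The INT statistic is a monotone function of lag-1
  autocorrelation with a closed-form value under AR(1), so parameter
  recovery is checkable without simulation error in the target itself.
  Richer HRF-convolved or 1/f models are deliberately out of scope: a
  green recovery test establishes that the estimator tracks
  autocorrelation, not that it is unbiased for real haemodynamics.
* **Defaults.** TR = 2 s and 150 frames per session match typical
  open-dataset resting-state acquisitions (COBRE-length runs at the
  common 2 s repetition time); the 24×24×24 grid with an inscribed
  ellipsoid mask (~7200 voxels) is the smallest brain-like geometry that
  still supports the ≥5000-voxel calibration tests. Baseline
  \(\phi = 0.3\) gives a true INT of 0.86 s, in the range of published
  sub-second occipital ROI means at this TR.
* **Between-subject variance** comes from Gaussian jitter on \(\phi\)
  (sd 0.05, truncated to [0, 0.95]), drawn independently per subject
  *and voxel*. A subject-level scalar would be more realistic but makes
  voxel-wise test statistics dependent across voxels, which the null
  calibration check (independent uniform p-values) implicitly assumes
  away. Welch/pooled t tests require nonzero within-group variance, hence
  jitter is on by default.
* **Planted effects** are compact regions (the `n` in-mask voxels nearest
  a centre) where patients receive a lower \(\phi\) than controls —
  shorter planted timescales, matching the direction of the published
  findings.
* **Motion.** Per-subject mean FD is lognormal (location log 0.15 mm for
  controls, log 0.22 mm for patients, sdlog 0.4): positive, right-skewed,
  patients shifted — the regime the two-phase matching algorithm is
  designed for. Frame-level motion spikes are not injected into the time
  series; FD and BOLD are coupled only through group membership.
* **Symptoms.** One PANSS-positive-like score per patient,
  \(20 - 5\cdot\mathrm{INT}_{\text{region 1}} + \mathcal N(0,4)\),
  truncated at zero; controls get `NA`. The negative slope encodes the
  hypothesis that more severe symptoms accompany shorter timescales.
* **No spatial smoothing** is applied: smoothing belongs to preprocessing,
  which is out of scope here, and unsmoothed voxels keep the voxel-wise
  nulls independent.

What a green test therefore does *not* establish: robustness to
haemodynamic confounds, physiological noise, spatial autocorrelation of
real BOLD, or motion artefacts entering the time series themselves.

## Null calibration, honestly

With no planted effect, the voxel-wise two-sample t p-values should be
uniform. They are *nearly* so: at T = 150 the INT estimator is
right-skewed (skewness ≈ 1.5), and with 20 subjects per group the t
reference distribution is followed imperfectly — the empirical CDF of the
p-values deviates from uniform by up to ~1.5% mid-range, and the extreme
tail is conservative (the p < 0.001 rate is ~0.0005 rather than 0.001).
Over ~7200 voxels a Kolmogorov–Smirnov test sits right at the α = 0.01
decision boundary (D ≈ 0.017 against a critical value of ≈ 0.019), so the
verdict is seed-dependent. The acceptance suite runs the KS check at a
pre-registered seed and the supra-threshold-rate check pooled over 20
seeds; the conservative tail means false-positive control — the property
that matters for cluster discovery — holds with margin.

## Voxel-wise mapping conventions

* **Pooled-variance t by default** at the voxel level (the mass-univariate
  convention under which such ROIs are discovered in SPM-style analyses);
  Welch by flag. ROI-level tests are always Welch.
* **Connectivity 18** by default (SPM's surface-or-edge neighbourhood);
  6 and 26 selectable. Components are labelled by BFS flood fill and
  cross-checked in the tests against an independent min-label-propagation
  oracle.
* **`min_cluster_size` 5 voxels**: no exact rule is derivable from the
  published cluster table, so it is exposed in config.
* **FDR at the peak.** "FDR-corrected" peak statistics are interpreted as
  voxel-level Benjamini–Hochberg q computed over all in-mask p-values and
  read out at each cluster's peak voxel — a documented convention, not a
  claim about the original analysis.
* **Coordinates.** Voxel indices are 0-based; reported peaks go through
  the NIfTI sform affine, so they are MNI millimetres when the input is
  MNI-registered. Ties for the peak (equal |t|) break toward the smallest
  linear index; cluster ordering is size descending, then peak |t|
  descending, making reports deterministic.

## Motion matching

FD follows the Power convention: per-frame sum of absolute backward
differences of the six realignment parameters, rotations mapped to arc
length on a 50 mm sphere (radius configurable); the first frame is 0 and
a subject is summarised by the series mean. Published FD-based exclusion
procedures often name only the software used, not the exact metric, so
the Power convention here is a documented choice; Jenkinson-style RMS
displacement would differ by a bounded factor and is not implemented.

The two-phase matching is operationalised deterministically:

1. While Welch p(HC FD, SZ FD) < α, remove the patient with the largest
   mean FD (never below `min_group`, default 10; running out is an
   error).
2. Repeatedly consider the control with the smallest mean FD and remove
   it only while that strictly decreases |Δ mean FD|.

"As similar as possible (p ≈ 1)" is deliberately *not* implemented as
maximising the Welch p: p is non-monotone in n as subjects are removed,
which makes a greedy p-optimiser ill-defined. The |Δmean|-decrease rule
is monotone, terminates, and is verified in the tests against an
exhaustive replay of the stated procedure. FD ties break by lexicographic
subject id, so results are pure functions of the input.

## ROI-level inference

* **Welch t** from (n, mean, sd) triples, so summary-level and raw-data
  calls agree exactly; Satterthwaite df; all p two-sided.
* **Hedges g** uses the pooled SD over \(n_1+n_2-2\) df and the
  small-sample correction \(J = 1 - 3/(4\,\mathrm{df} - 1)\). The
  correction is not optional: without it the published worked examples do
  not round to their printed values.
* **Bonferroni** multiplies by the family size, default m = 5 (one test
  per discovery ROI per sample and analysis family), capped at 1. Some
  published corrected correlations imply larger families, so m is
  configurable and logged.
* **ANCOVA-style effects** use an additive OLS model with Type II sums of
  squares (each term assessed by dropping it from the full model). No
  interaction terms: none are identifiable from the published design and
  the additive model is the stated analysis.
* **2×2 χ²** uses the Yates continuity correction by default; only the
  corrected statistic reproduces both published balance checks from their
  printed counts. (One published p alongside those statistics is
  inconsistent with its own χ² at 1 df; the package reports the p implied
  by the statistic.)

## Pipeline

`run_pipeline` executes the study design from one JSON config (JSON
rather than YAML: the target environment ships a JSON parser only):
INT maps → discovery t-map and frozen ROIs → ROI means everywhere →
pre-matching ROI comparisons (discovery excluded; the exclusion is
logged as a double-dipping guard) → FD matching and post-matching
reanalysis on all datasets → FD–INT correlations pre/post → symptom
correlations, sex ANCOVAs (skipped with a log note for single-sex
datasets) and medication-dose main effects. ROIs are defined once, before
motion matching, and reused unchanged afterwards. Every output is a pure
function of the config (including seeds); a config hash is written into
the report, and `force = FALSE` reuses a cached run with a matching hash.

## Known limitations

* The AR(1) world has no haemodynamic response, physiological noise,
  spatial smoothness, or frame-level motion corruption; conclusions about
  robustness to those must come from real data.
* The NIfTI-1 reader/writer is minimal (single-file images, common
  datatypes, sform affine); it is validated against nibabel but does not
  support two-file pairs, extensions, or exotic datatypes.
* The FDR-at-peak and Phase-2 stopping rules are defensible readings of
  underspecified descriptions, not reconstructions of the original code.
* `linear_main_effects` assumes a full-rank additive design and rejects
  collinear terms rather than aliasing them silently.
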