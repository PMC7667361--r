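---
title: "Functional connectivity density mapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the connectivity-density statistic and the inference chain around it, the
synthetic cohort model used to validate both, and the numerical and design
choices made where the methodology is genuinely open.

## The statistic

Resting-state BOLD fMRI measures a slow (< 0.1 Hz) spontaneous signal per
voxel. Functional connectivity density (FCD) summarizes each gray-matter
voxel's embedding in the whole-brain correlation structure by a single
degree count: the number of other mask voxels whose full-time-course
Pearson correlation with it exceeds a threshold r₀. The degree is split by
anatomical (Euclidean, world-mm) distance between voxel centers:

- **sFCD** (short-range): suprathreshold partners within a 12 mm radius
  sphere — local, tissue-neighborhood connectivity;
- **lFCD** (long-range): suprathreshold partners beyond 12 mm —
  distributed network connectivity.

Edges require r **strictly greater** than r₀ = 0.25 and are positive-only:
anticorrelations never count. Both conventions follow the classical FCD
literature; a configurable switch exists but is off by default. Ties at
exactly 12 mm belong to the short range. The sphere-count definition of
sFCD is used, not the growing-connected-cluster variant found elsewhere in
the degree-mapping literature.

Per subject the raw counts k are turned into two products:

1. **Z maps** — (k − mean)/SD over the mask (population-SD convention),
   then Gaussian-smoothed at 6 mm FWHM. These feed the voxel-wise group
   statistics; standardization precedes smoothing.
2. **k/k₀ maps** — k divided by the whole-mask mean count, unsmoothed.
   These feed ROI extraction, Cohen's d, and clinical correlations, where
   a ratio scale ("this voxel has 1.5× the average connectivity") is the
   interpretable quantity.

Both are always emitted; which one the GLM consumes is a configuration
choice defaulting to the smoothed Z maps.

## Preprocessing

The temporal chain is fixed and ordered: discard the first 10 volumes
(scanner saturation), per-voxel linear detrend, zero-phase band-pass at
0.01–0.1 Hz, then nuisance regression. The filter is a frequency-domain
mask — exactly rectangular in the passband with a raised-cosine taper of
half-width 0.002 Hz at each edge — chosen because its spectral behavior is
exact and testable in closed form (a 0.05 Hz sinusoid passes within 5%; a
0.2 Hz sinusoid is attenuated by more than 90%).

Nuisance regressors are the Friston-24 motion expansion (the six
rigid-body parameters, their one-volume lags, and the squares of both;
the lag row at the first volume is zero-padded, with a drop-first
alternative available) plus optional tissue mean signals. Because the data
are filtered before regression, the regressors are passed through the
same band-pass first; regressing raw regressors against filtered data
would reintroduce out-of-band variance. This is standard practice and can
be disabled.

One structural constraint is worth knowing: the 0.01–0.1 Hz passband of a
series with T volumes at TR = 2 s holds roughly 0.18·T complex Fourier
coefficients of freedom. With short series (under ~100 volumes) the 24
motion regressors can span most of that subspace and annihilate the
signal. At the study scale (230 retained volumes, ~84 real degrees of
freedom in band) this is a non-issue, but very short simulations should
skip nuisance regression.

Head motion is quantified by Jenkinson's frame-wise displacement: for each
adjacent volume pair, the RMS displacement of the relative rigid-body
transform over an 80 mm sphere, FD = √(R²/5·tr(AᵀA) + bᵀb), using full
rotation matrices rather than a small-angle approximation. Subject
exclusion applies strict per-axis limits (< 2 mm translation, < 2°
rotation) relative to the first retained volume. Note that FD is exactly
invariant to a constant translation offset only while rotations are
constant; varying rotations couple the offset into the relative transform
at order θ·offset.

## Group inference

Voxel-wise ordinary least squares of the per-subject maps on
[intercept, group, age, gender, mean FD], covariates mean-centered,
gender coded 0/1. The group coefficient's t statistic (df = n − rank) is
the test statistic; with no covariates this reduces exactly to the
two-sample pooled-variance t, which the tests verify algebraically.

Cluster-extent correction is a Monte-Carlo simulation in the AlphaSim
family: fill the mask with unit Gaussian noise, smooth to a stated FWHM,
re-standardize within the mask, threshold two-tailed at the voxel p, label
clusters under the rmm-connectivity rule (neighbors are voxels whose
centers lie within rmm = 5 mm — on a 3 mm grid that means faces and edges
but not corners, derived from voxel size at run time), and record the
maximum cluster size over both signs. The extent threshold k_min is the
smallest k whose null exceedance probability is ≤ α. Positive and
negative clusters are labeled separately and pooled for the maximum, and
the identical rule is applied to real t maps (thresholded at the
t-distribution quantile for the map's df).

The smoothness fed to the simulation defaults to the FWHM actually applied
to the maps (6 mm). Statistic maps can carry *intrinsic* smoothness beyond
the applied kernel — for the synthetic data the local correlation field
adds to it, giving an effective ~8–9 mm — which makes the fixed-FWHM null
mildly anticonservative. `estimate_fwhm()` implements the classical
neighbor-correlation estimator (the FWHM of the kernel that would give
white noise the observed lag-1 spatial autocorrelation) and can be passed
to `alphasim_config()`; the calibration tests use it, the pipeline default
does not.

Post hoc, surviving clusters are reported with size, peak world-mm
coordinate, peak t, sign, and Cohen's d — (mean₁ − mean₂)/pooled SD,
n₁+n₂−2 denominator — computed on per-subject mean k/k₀ within the
cluster. Clinical analysis is a partial correlation (Pearson correlation
of residuals after removing age and gender, p from
t = ρ√(df/(1−ρ²)), df = n − 2 − #covariates) over the full region × metric
grid, corrected by Benjamini–Hochberg FDR across that entire family. The
family choice matters and is deliberately the whole grid; per-metric
families would be less conservative.

Demographic summaries use the pooled-variance Student t computed from
group means and SDs (so printed cohort tables are reproducible inputs) and
the Pearson chi-square without continuity correction for 2×2 gender
tables.

## Seed-based connectivity

Each surviving long-range cluster can be backtracked: its unweighted mean
time course is correlated with every mask voxel, the map is Fisher
r-to-z transformed (atanh, with |r| clamped at 1 − 10⁻⁷ so seed voxels
stay finite), and group-level maps are built two ways. The within-group
connectivity pattern is a one-sample t test across subjects with BH-FDR
over the mask, read at adjusted p < .001, intersected with a positive
group-mean constraint — negative correlations never define the pattern.
The between-group comparison reuses the identical GLM + cluster-extent
code path as the FCD comparison (one implementation, verified by a shared
test), reporting Cohen's d on extracted mean z.

## The synthetic cohort model

The generator exists so that every stage above has a ground truth. It
emulates a two-group resting-state study — 27 patients and 27 matched
controls, 240 volumes at TR = 2 s, 3 mm isotropic voxels, an ellipsoidal
"gray-matter" mask inscribed in a 24³ grid — with this per-voxel signal
model:

- **Network signal**: per network, a sum of 8 sinusoids with frequencies
  drawn uniformly in 0.01–0.1 Hz and random phases, standardized. Exactly
  band-limited by construction (at finite length a periodogram shows
  ~1% leakage outside the literal band from edge-frequency windowing; the
  spectral test allows two frequency-resolution bins of margin). Voxels of
  a network's ROIs share its signal at a coupling weight, producing
  long-range edges between distant same-network ROIs.
- **Local field**: an independent Gaussian field, spatially smoothed at
  8 mm FWHM per volume and mixed at a local gain, producing short-range
  correlation that decays as exp(−d²/4σ²).
- **Noise and drift**: AR(1) noise (lag-1 coefficient 0.3) scaled by
  1/SNR (SNR 1.4), a linear drift of 0.02 units/volume, and a baseline of
  100 units.
- **Motion**: six-parameter random-walk traces with per-subject severity;
  translation steps ~0.02 mm, rotations scaled 1/50 of that (≈ equal FD
  contribution at an 80 mm head radius), giving mean FD ≈ 0.1 mm, the
  scale reported in motion-matched clinical cohorts.

Planted group effects, all scaled by a per-patient severity drawn from
N(1, 0.15) truncated at 0: an 80% coupling deficit in one network ROI (the
lFCD-decrease region), a 60% local-gain deficit in one sphere (the
sFCD-decrease region), and a 100% local-gain boost in another (the
sFCD-increase region). These magnitudes are free parameters of the
simulation, chosen once so the full pipeline detects the effects at
n = 27 per group; they are design choices of this package, not empirical
claims. The coupling deficit is deep because band-pass filtering
concentrates noise power into the passband and *raises* all correlations:
a control same-network pair sits near r ≈ 0.5 after filtering, and a
shallow deficit would leave patients hovering at the r₀ = 0.25 edge
threshold rather than below it. A worthwhile detail: both arms of the
planted network lose long-range edges (each loses its partner), so the
group comparison correctly finds two decrease clusters, one per arm.

Clinical scores are linear in severity plus Gaussian noise, clipped to
instrument ranges (PSQI 0–21, STAI 20–80, BDI-II 0–63, symptom duration
≥ 0.25 y). Intercepts and noise SDs emulate a chronic-insomnia cohort
against good-sleeper controls (patients PSQI ≈ 13.3 ± 2.5 vs controls
0.9 ± 1.1); the PSQI and duration slopes tie the scores to the planted
severity so correlation recovery is testable. Age and gender are matched
by construction (17F/10M per group).

Determinism: one global seed expands to per-subject substreams by a
counter scheme (seed·1009 + subject index, mod 2³¹−1), so cohorts are
bitwise reproducible and any single subject can be regenerated alone.

What the generator does **not** emulate: scanner artifacts (spikes,
ghosting, distortion), slice-timing offsets, anatomical variability and
registration error, physiological (cardiac/respiratory) structure,
spatially varying SNR, or motion-by-signal interaction (motion traces
influence FD and exclusion but do not corrupt the signal). Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
under a known generative model, not robustness to real-world artifacts.

## Numerical choices

- **Correlation as cross products**: time courses are centered and
  unit-normalized once; blocks of the correlation matrix are single BLAS
  calls. Counts are exactly independent of the block size (verified
  integer-exactly), and an exhaustive per-pair oracle confirms them on
  small cohorts. Zero-variance voxels have undefined correlations; they
  contribute no edges, stay in the mask with k = 0, and are counted in the
  output.
- **Smoothing**: separable discrete Gaussian, kernels truncated at 4σ,
  applied as banded-matrix multiplies. Maps are smoothed embedded in zeros
  and divided by the smoothed support indicator, so constants are
  preserved and boundary voxels are not attenuated. With 3 mm voxels and
  6 mm FWHM the one-voxel impulse-response ratio is exactly 0.5.
- **Z-scoring** uses the population (n) SD; a zero-SD map is an error, as
  is a zero mean count for k/k₀ normalization.
- **Degenerate designs**: constant or collinear nuisance columns are
  dropped with a warning; a rank-deficient group design is an error naming
  the collinear columns. Exact (zero-residual) voxel fits report t = 0
  rather than 0/0.
- **Cluster labeling** is flood fill over precomputed neighbor offsets;
  labels are assigned in array order, making results independent of
  traversal order.

## Problem sizes

The default simulation profile (24³ grid, 54 subjects, 240 volumes) runs
a full pipeline in minutes on one CPU. The test and acceptance suites use
reduced profiles chosen as the package's desk-scale validation sizes:
8–10³ grids for oracle equivalence, 12³ for Monte-Carlo calibration
(2000-iteration null comparisons; 200 replicate family-wise error runs),
and 16³ with 200 volumes and the full n = 27 + 27 for end-to-end
planted-effect recovery. Recovery is scored by Dice overlap between
surviving clusters and the planted masks (> 0.3 required; ~0.5–0.7
observed).

## Known limitations

- The cluster-extent null assumes Gaussian random fields of stated
  smoothness; heavy-tailed or spatially nonstationary data violate it, as
  they do for the original Monte-Carlo tools this reimplements.
- FCD is a relative, within-subject standardized measure; global
  connectivity differences between groups are largely removed by
  Z-scoring and k/k₀ normalization and can even induce compensatory
  apparent increases elsewhere in the mask.
- The one-sample FDR mask rule ("adjusted p below the voxel threshold")
  is one reading of mixed threshold conventions in the applied literature;
  it is configurable.
- No spatial preprocessing: data are assumed registered to a common grid.
  Real studies need realignment, normalization and segmentation upstream.
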