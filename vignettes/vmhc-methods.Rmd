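---
title: "Interhemispheric functional symmetry: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric functional symmetry: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The two cerebral hemispheres respond to many stimuli in topographically
matched ("homotopic") locations. A simple, powerful summary of this
coupling is *voxel-mirrored homotopic connectivity* (VMHC): the Pearson
correlation between each voxel's time series and the time series of its
mirror-image voxel across the midsagittal plane. `vmhc` implements a
complete VMHC pipeline for 4D time-series volumes — template
symmetrization, per-subject symmetry maps with autocorrelation-corrected
inference, two-group contrasts with Monte-Carlo cluster-extent
correction, and corpus-callosum volume statistics — together with a
synthetic-data generator that provides ground truth for every stage.

# Geometry and the mirror convention

Volumes use an even x-dimension with the mirror plane between the two
central voxel columns; voxel `i` pairs with voxel `nx + 1 - i`. Every
voxel therefore has a *distinct* homotopic partner and there is no
self-paired midline column. Physical coordinates put x = 0 on the mirror
plane, so mirroring is simply `(x, y, z) -> (-x, y, z)`
(`mirror_coordinates()`).

# Template symmetrization

Real brains are not mirror-symmetric (Yakovlevian torque, petalia), so a
template can be symmetrized before homotopic comparison by solving an
unconstrained optimization: find polynomial warp parameters `a`
minimizing the mean squared intensity error between each left-hemisphere
voxel and the warped image of its mirror position,

    cost(a) = mean_x [ b(f_a(r(x))) - b(x) ]^2 ,

with `b` evaluated by trilinear interpolation and `f_a` a trivariate
polynomial (full monomial basis of total degree <= 5 by default, 168
coefficients; the degree is configurable because derivative-free fits of
168 parameters are a cluster-scale computation — tests use degree <= 2,
which exercises the identical code path). Coordinates are pre-normalized
to [-1, 1] per axis; without this the monomial design matrix is so badly
conditioned that the simplex stalls. Minimization is Nelder-Mead with
random restarts (identity plus coefficient jitter of 0.01 on normalized
coordinates); the restart with the lowest converged cost wins, and a
hard iteration cap flags non-convergence rather than erroring.

Two contracts worth noting:

* Out-of-domain samples during cost evaluation take fill value 0 and are
  *included* in the mean (exclusion is selectable). The synthetic
  templates taper smoothly to a near-zero background, so the fill
  contract is benign there, as it is for skull-stripped real templates.
* The reference analysis reports hemispheric MSE in mm² although the
  quantity is a squared intensity discrepancy; we report the raw mean
  squared intensity difference and leave the unit unexplained, as it is
  in the source.

Whether one warp is fitted on the group template and applied to all
subjects or fitted per subject is ambiguous in the source description;
the pipeline fits once on the template (per-subject fitting is available
by calling `fit_symmetrization()` per subject).

# Per-subject symmetry maps

Runs are concatenated after discarding the first 4 volumes of each run
(magnetization transients). Optional preprocessing mirrors the usual
resting-state stack: cubic-spline detrending (knots every 128 s by
default), temporal Gaussian filtering ("kernel width = 4 s" is read as
FWHM, the SPM convention; a sigma reading is selectable), and nuisance
regression.

The symmetry index is the homotopic Pearson correlation `r`; inference
uses Fisher's transform `z_f = atanh(r)` and the corrected score
`z = z_f * sqrt(df - 3)`. The source prints `arctan` for the transform
but cites Fisher and uses the `sqrt(df - 3)` scaling, which presumes the
`atanh` variance `1/(df - 3)`; we treat the printed `arctan` as a typo,
implement `atanh`, and provide `variant = "arctan"` for literal
replication.

Serial correlation in the time series inflates the nominal degrees of
freedom, so `df` is the *effective* sample size from the
autocorrelation plug-in

    1/df = 1/N + (2/N) * sum_{j>=1} ((N-j)/N) * rho_xx(j) * rho_yy(j) ,

estimated over 1,000 randomly sampled homotopic pairs and averaged
(`estimate_effective_df()`); a single study-level scalar is used for all
voxels, as in the reference analysis. Design choices: the lag sum runs
to N-1 with the biased (divisor-N) autocorrelation estimator, which
keeps the sum stable; the source calls the approach "permutation-based"
but describes no permutation of time order, so none is implemented.
A property of this plug-in worth knowing: when the two series of a pair
are themselves correlated (rho > 0), the *sampling noise* of their
autocorrelation estimates is correlated too, which biases the full-lag
sum upward and the df estimate below N even for white noise. For
independent pairs (how the estimator is validated, and how the null
data are built) the estimate is unbiased to within a few percent.

# Group inference

Directional pooled-variance two-sample t-maps are formed on the
corrected-z maps and converted voxelwise to z-equivalents, so the
voxel-forming threshold z = 2.32 (one-tailed p = 0.01) means the same
thing for subject-level maps, group maps and Monte-Carlo null images.

Cluster-extent correction follows the Monte-Carlo recipe: build
surrogate symmetry maps by correlating each subject's series with its
*flipped, phase-scrambled* image; form the null group t-map; estimate
the 3D spatial autocorrelation function (ACF) of that map (via the
power spectrum), averaged over several runs; convolve white noise with
the kernel to generate null statistic images; pool supra-threshold
18-connected cluster sizes into a null distribution; and keep real
clusters at least as large as the critical size `k_crit`, the smallest
size whose null tail probability falls below the cluster p (0.001 by
default). Surviving clusters are finally masked by a one-sample
right-tailed test of the favoured group's mean corrected z at
p < 0.0005 and re-measured, so that "more symmetric than the other
group" never survives where symmetry itself is absent. Cohen's d maps
and the physical volume with d > 0.8 complete the stage.

Dialect decisions (the source text underdetermines both):

* *Phase scrambling*: one random phase field per subject, applied to
  every timepoint of the flipped series. This destroys homotopic
  spatial alignment (the null of interest) while preserving each
  voxel's temporal autocorrelation — precisely the nuisance the
  effective-df correction addresses. Independent per-timepoint draws
  are available by flag. Scrambling preserves Fourier amplitudes
  exactly and pins the DC phase, so means and power spectra are
  untouched.
* *Noise convolution*: null images are white noise convolved with the
  ACF kernel itself, as the source describes. Strictly, convolving
  with the ACF squares the power spectrum relative to the source map
  (the spectrally exact filter would be the square root of the ACF's
  spectrum), so the null images are slightly smoother than the t-map
  and the resulting `k_crit` errs conservative. We keep the described
  construction and verify the end-to-end family-wise error rate
  empirically (below).

`k_crit` uses "survive iff k >= k_crit" with `k_crit` the smallest size
with tail probability < p; because the source mixes "p < 0.001" with
"> 55 voxels", the raw critical size is exposed so either convention
can be applied.

# Corpus-callosum statistics

The five FreeSurfer segments are regrouped into posterior (posterior +
mid-posterior + central) and anterior (mid-anterior + anterior)
sections. Because a cross-sectional (area-like) structure scales as
volume^(2/3), relative sizes are section / brain^(2/3); note the ratio
is not dimensionless — isotropic scaling of the whole head by `s`
scales it by `s` — which the tests assert as the intended behaviour.
Group comparisons are one-tailed pooled-variance t-tests (Welch by
flag) with the percent difference reported as
`(mean_favoured - mean_other) / mean_other * 100`; the base group of
the source's printed percentage is unstated, so the convention is
documented rather than inferred. The CC-brain association is a plain
Pearson correlation on raw volumes.

# The synthetic world

`sim_config()` fixes the generative model:

* **Grid**: 16^3 voxels of 2 mm by default (normalized functional
  resolution); even x-dimension enforced.
* **Templates**: smoothed Gaussian fields (8 mm FWHM by default,
  matching the spatial smoothing that makes real templates nearly
  symmetric), windowed by a smooth radial taper so the "brain" sits in
  a near-zero background, then averaged with their own x-flip — making
  mirror symmetry *exact*, bitwise.
* **Series**: each homotopic pair is `sqrt(rho) * shared +
  sqrt(1-rho) * unique`, built from standardized AR(1) processes with
  common coefficient phi, so the population pair correlation is exactly
  `rho` independent of phi. Defaults: N = 702 timepoints at TR = 2 s
  (the concatenated-run length of the reference analysis), phi = 0,
  smoothing off. Spatial smoothing, when enabled, is applied per
  timepoint after pair construction with FWHM = sigma * sqrt(8 ln 2);
  it raises realized neighbourhood (and homotopic) correlations, so the
  per-pair target is a *pre-smoothing* ground truth.
* **Group datasets**: group A carries `baseline + delta` inside a
  mirror-symmetrized effect region, baseline elsewhere; group B is
  baseline everywhere; per-subject seeds are master seed + subject
  index.
* **Callosal tables**: segment volumes are truncated normals around
  FreeSurfer-realistic means (950/450/450/500/900 mm^3, 15% CV); total
  brain volume is built from the standardized total CC plus independent
  noise so that the population CC-brain correlation equals a stated
  value (0.46 by default).

What the generator does *not* emulate: hemodynamics, motion and
scanner artifacts, spatial nonstationarity, EPI distortion, and any
anatomical realism beyond smoothness and background. A green test
therefore establishes the *statistical* correctness of the machinery —
calibration, recovery, invariances — not robustness to real-scanner
nuisances.

# Calibration and recovery evidence

The acceptance suite (`tests/testthat/test-acceptance.R`) computes, at
documented reduced scale:

1. **Effective-df oracle** — matched independent AR(1) pairs (phi =
   0.5, N = 702): the 1,000-pair estimate agrees with the closed form
   `1/df = 1/N + (2/N) sum ((N-j)/N) phi^(2j)` within 10%; white noise
   returns N within 5%.
2. **Calibration** — on null data the corrected-z exceedance at z =
   2.32 matches 0.01 within the binomial 95% CI over >= 10^4 pairs;
   and across 200 null group datasets (24^3 grid, 5 subjects/group, 40
   timepoints, 500 null images, 2 ACF runs) the family-wise rate of
   any surviving cluster is consistent with the nominal cluster p =
   0.001.
3. **Recovery** — a planted delta-rho = 0.3 in a 5^3 block (baseline
   0.2, 10 vs 10 subjects, 700 timepoints, AR(1) phi = 0.3) is
   detected, with block overlap, in >= 80% of 20 seeded replicates,
   and the Cohen's d > 0.8 volume overlaps the block.
4. **Symmetrization** — a known degree-<=2 distortion of a symmetric
   16^3 template is undone to below half the initial hemispheric MSE
   by a 5-restart fit (in practice to well under 1%).
5. **Oracle equivalences** — Rcpp cluster labeling vs brute-force BFS
   on random maps for all three connectivities; exact spectrum
   preservation under phase scrambling; exact reproduction of linear
   fields by trilinear interpolation; `fisher_z == atanh` to 1e-12.
6. **Morphometry** — exact CC conservation under regrouping, the
   s^3 -> s scaling law, and null-uniform group-test p-values (KS).

The reduced scales (subject counts, timepoints for the null datasets,
2 ACF runs instead of 10, 500 null images instead of 10,000) were fixed
when the experiments were designed, to fit a single-CPU test budget;
the statistical levels and tolerances are the stated ones. With the
nominal cluster p at 0.001 and 200 datasets the family-wise check
mostly guards against anti-conservatism — it cannot distinguish exact
calibration from mild conservatism (expected from the ACF-convolution
dialect), which is the appropriate reading of a green result.

# Numerical notes and limitations

* Trilinear interpolation treats the voxel-centre bounding box as the
  domain; out-of-domain reads use a declared fill value.
* FFT-based operations (smoothing, scrambling, ACF, noise convolution)
  are periodic; templates are tapered to zero at the boundary to keep
  wraparound harmless, and null statistic images are standardized per
  image before thresholding.
* Zero-variance voxels are masked out of correlation maps and excluded
  from pair sampling; `|r| = 1` maps to a masked value, never an
  infinite z.
* The effective-df estimate is clipped into (3, N]; `corrected_z()`
  refuses df <= 3 rather than returning complex standard errors.
* Nelder-Mead at degree 5 (168 parameters) is the faithful but slow
  configuration; expect cluster-scale runtimes, and prefer lower
  degrees unless the full family is required.
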