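# vmhc

Interhemispheric functional-symmetry analysis of 4D brain time-series
volumes, for researchers who want a self-contained, testable
implementation of voxel-mirrored homotopic connectivity (VMHC) with
honest inference.

The pipeline:

1. **Template symmetrization** — fit a trivariate polynomial warp
   `f_a` minimizing the homotopic mean squared error
   `mean_x [ b(f_a(r(x))) − b(x) ]²` over left-hemisphere voxels
   (`r(x, y, z) = (−x, y, z)`, trilinear sampling, Nelder–Mead with
   random restarts), to counteract natural brain asymmetries before
   mirror comparisons.
2. **Symmetry maps** — per subject, the symmetry index is the Pearson
   correlation `r` of each voxel's series with its mirrored partner's;
   inference uses Fisher's `z_f = atanh(r)` and the corrected score
   `z = z_f · √(df − 3)`, where the effective degrees of freedom under
   temporal autocorrelation come from the plug-in
   `1/df = 1/N + (2/N) Σ_j ((N−j)/N) ρ_xx(j) ρ_yy(j)`
   averaged over 1,000 random homotopic pairs.
3. **Group inference** — directional two-sample t-maps (one-tailed
   α = 0.01, voxel-forming z = 2.32), cluster-extent correction from a
   Monte-Carlo null: flipped phase-scrambled surrogate maps → null
   t-map → spatial ACF kernel (averaged over runs) → noise-convolved
   null images → critical 18-connected cluster size at p < 0.001 →
   group-mean masking at p < 0.0005; plus Cohen's d maps and the
   brain volume (cm³) with d > 0.8.
4. **Corpus-callosum statistics** — five segments regrouped into
   posterior/anterior sections, normalized by total brain volume to the
   2/3 power, one-tailed group t-tests and the CC–brain correlation.
5. **Synthetic data** — exactly mirror-symmetric templates, 4D series
   in which each homotopic pair has population correlation exactly ρ
   (AR(1) temporal noise, optional Gaussian smoothing), group datasets
   with planted effects, and callosal tables — everything the pipeline
   consumes, with known ground truth.

Volumes are read and written as NIfTI-1 (`.nii` / `.nii.gz`; the
package carries a minimal codec validated against nibabel), tables as
CSV/TSV, warps and configuration as JSON.

## Worked example

Ten vs ten synthetic subjects, 700 timepoints, with the homotopic
correlation raised from 0.20 to 0.50 inside a 5×5×5 block (plus its
mirror image):

```r
library(vmhc)

grid  <- c(12L, 12L, 12L)
cfg   <- sim_config(grid_shape = grid, n_timepoints = 700L,
                    ar_coefficient = 0.3, seed = 501)
block <- array(FALSE, grid); block[2:6, 4:8, 4:8] <- TRUE
spec  <- group_spec(10L, baseline_rho = 0.2, effect_region = block,
                    effect_delta_rho = 0.3, seed = 501)
dat   <- generate_group_dataset(spec, cfg)

df <- mean(vapply(c(dat$A, dat$B), function(s)
  estimate_effective_df(s, n_pairs = 1000, seed = 1)$df, numeric(1)))
mapsA <- lapply(dat$A, function(s) symmetry_map(s, df = df)$z)
mapsB <- lapply(dat$B, function(s) symmetry_map(s, df = df)$z)

g <- group_contrast(dat$A, dat$B, mapsA, mapsB, df = df,
                    n_null_images = 500L, acf_runs = 2L,
                    voxel_mm = 2, seed = 99)
round(df, 1)
g$cluster_null
g$clusters$table
g$effect_size$volume_A_gt_B_cm3
```

```
#> [1] 568.1
#> <cluster_null> 500 images, 235 null clusters, k_crit = 8 at p < 0.001
#>   cluster   k     peak ix iy iz x_mm y_mm z_mm
#> 1       1 256 8.592851  5  6  8   -3   -1    3
#> [1] 2.448
```

Reading: temporal autocorrelation (φ = 0.3) shrinks the nominal 700
degrees of freedom to an effective ~568; the Monte-Carlo null says a
supra-threshold (z > 2.32) cluster must span ≥ 8 voxels to be
significant at p < 0.001; one cluster of 256 voxels survives — the
planted 2 × 5³ region plus a thin fringe — peaking at z ≈ 8.6 inside
the block, and 2.45 cm³ of brain shows Cohen's d > 0.8 in favour of
group A.

On real data the entry points are the same: `read_volume()` your runs,
`concatenate_runs()`, optionally `detrend_series()` /
`temporal_filter()` / `nuisance_regress()` and
`apply_symmetrization()` with a warp from `fit_symmetrization()`, then
`symmetry_map()`, `group_contrast()` and `label_clusters()` with your
atlas volume. `run_pipeline(pipeline_config(...))` chains the stages
and writes a manifest; `inst/cli/vmhc` exposes
`simulate | symmetrize | vmhc | group | morpho | run` subcommands.

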