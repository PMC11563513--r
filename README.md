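# octaphen

Retinal microvascular phenotyping from OCT-angiography, with the
clustered-eye statistics of a two-eye observational design.

OCT-angiography (OCT-A) images the perfused retinal microvasculature
without dye. Because the retina shares developmental origin and physiology
with the brain's small vessels, quantitative retinal phenotypes are
candidate biomarkers for cerebral small vessel disease (SVD) and for
monitoring treatments — for example CPAP therapy in obstructive sleep
apnoea — that act on the microvascular bed. `octaphen` implements the full
image-to-inference chain for 3 mm x 3 mm scans of the superficial vascular
complex:

1. **Segmentation** — 2-D optimally-oriented-flux (OOF) vessel
   enhancement: per pixel and scale *r*, the outward flux of the smoothed
   image gradient through a circle of radius *r* forms a 2x2 matrix whose
   negated smaller eigenvalue (intensity-weighted, maximized over scales)
   is the vesselness; Otsu thresholding and deterministic cleanup give a
   binary mask.
2. **Vascular graph** — topology-preserving thinning, per-pixel radii
   from the Euclidean distance transform with sub-pixel refinement, a
   node/segment centerline graph, spur pruning, and a large/small-vessel
   split at 20 um caliber.
3. **Phenotype panel** — foveal and parafoveal vessel density, foveal
   avascular zone (FAZ) area, mean tortuosity (arc/chord), branching
   points (degree-3 nodes), mean bifurcation distance, mean radius, the
   branching symmetry ratio, and a Murray's-law deviation score: the
   two-sample Kolmogorov–Smirnov distance between the distributions of
   parent radius cubes and summed daughter cubes, which are equal under
   Murray's law *r_p^3 = r_1^3 + r_2^3*.
4. **Association statistics** — Gaussian generalized estimating equations
   (exchangeable working correlation, cluster-robust errors) with both
   eyes clustered by participant and standardized coefficients; per-eye
   longitudinal adherence comparisons (t-test / Mann–Whitney with a
   normality gate); GEE of phenotype change on CPAP usage; OSA severity
   and CPAP adherence categorization; macular thickness comparisons.
5. **Synthetic data** — a Murray-law vascular tree and angiogram
   generator with analytic ground truth, and a two-eye cohort simulator
   with known standardized effects, so every stage is testable without
   patient data.

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` (simulate scans, segment and recover phenotypes, sweep
Murray exponents, run the cohort association suite) are thin drivers over
the package functions and write their tables under `results/`.

## Worked example

```r
library(octaphen)

# a synthetic macular scan with known ground truth
tree <- generate_tree(tree_spec(seed = 3))
mask <- rasterize_tree(tree, image_size_px = 512, fov_mm = 3)
scan <- render_angiogram(mask, speckle_var = 0.1, seed = 1)

# segment it and compare against the rasterized truth
seg <- segment_angiogram(scan)
dice_coefficient(seg, mask)
#> [1] 0.9239484

# the phenotype panel on the ground-truth mask
rec <- compute_phenotypes(mask)
t(round(as.data.frame(rec), 3))
#> parafoveal_vd                    0.021
#> foveal_vd                        0.142
#> branching_points                42.000
#> faz_area_mm2                     0.286
#> tortuosity_large                 1.023
#> tortuosity_small                 1.016
#> radius_large_um                 14.662
#> radius_small_um                  6.663
#> ks_score                         0.214
#> symmetry_ratio                   0.687
#> bifurcation_distance_large_um       NA
#> bifurcation_distance_small_um  135.151
#> n_bifurcations                  42.000
#> vessel_px                     7115.000
```

At this moderate speckle level the segmentation overlaps the truth with
Dice 0.92 (0.96 at zero noise). The FAZ area is within 1% of the analytic
pi x 0.3^2 = 0.283 mm^2; `branching_points` counts the degree-3 junctions
of the pruned graph, and the large/small metrics refer to the networks
above and below 20 um caliber. `bifurcation_distance_large_um` is `NA`
because no large-caliber segment joins two junctions on this tree —
undefined metrics are reported as missing, never zero. The default
generator surrounds the FAZ with a capillary arcade whose junctions do
not obey Murray's law, so the 42 counted junctions include them and
`ks_score` sits above zero; the Murray-validation experiments in
`analysis/03_murray_deviation.R` use pure trees, where the score at the
exact exponent stays at or below 0.15 after rasterization.

```r
# two-eye cohort with a planted standardized effect, analyzed by GEE
tab <- generate_cohort(cohort_sim_params(
  n_participants = 500,
  effect_sizes = list(pvs_bg_count = c(foveal_vd = 0.4)),
  within_participant_corr = 0.5, seed = 1))$table
fit_gee_crosssectional(preprocess_cohort(tab), "pvs_bg_count", "foveal_vd")
#>        outcome phenotype standardized_beta ci_low ci_high  p_value n_eyes n_participants n_excluded alpha
#>   pvs_bg_count foveal_vd             0.394  0.336   0.451  6.5e-41   1000            500          0 0.472
```

The planted standardized beta of 0.40 is recovered (0.394, 95% CI from
the cluster-robust sandwich variance), with the exchangeable working
correlation `alpha` estimating the fellow-eye residual correlation;
`n_participants` counts clusters, `n_eyes` the analyzed rows.

## Layout

```
R/                  package implementation (generators, segmentation,
                    graph, phenotypes, GEE/statistics, pipeline I/O)
analysis/           numbered workflow scripts writing results/ tables
scripts/acceptance.R  validation quantities -> JSON
tests/testthat/     unit, property, and acceptance tests
vignettes/methods.Rmd  models, estimator choices, validation design
```
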