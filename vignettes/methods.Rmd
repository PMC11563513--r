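---
title: "Retinal microvascular phenotyping: models, estimators, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal microvascular phenotyping: models, estimators, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaphen)
```

## Scope

`octaphen` quantifies the retinal superficial vascular complex (SVC) from
en-face OCT-angiography scans of a 3 mm x 3 mm macular field, and analyzes
the resulting phenotype panel with the clustered-eye statistics appropriate
for a two-eye observational design. Because OCT-A patient data cannot be
redistributed, the package ships first-class synthetic generators — a
vascular-tree/angiogram simulator and a two-eye cohort simulator — with
analytic ground truth, so every stage of the pipeline is testable end to
end. This vignette records the models, the estimator choices with their
rationale, and what the validation experiments do and do not establish.

## The phenotype panel

From a binary vessel mask with a known physical scale (um/px), the package
computes:

* **Vessel density** in a foveal circle (1 mm diameter) and a parafoveal
  ring (1–3 mm), both image-centered: the exact fraction of vessel pixels
  in the region. The region geometry follows the ETDRS convention for 3 mm
  scans and is configurable.
* **FAZ area**: the largest connected vessel-free area among background
  components inside a central search disk (1.5 mm diameter by default),
  converted to mm^2. Restricting the component search to the central disk
  is essential: on any mask whose vasculature does not enclose the center,
  the outer background is one huge component and would otherwise always
  win. For an empty mask the FAZ degenerates to the whole search disk.
* **Centerline graph metrics**: the mask is thinned to a one-pixel
  skeleton, radii are assigned from the Euclidean distance transform, and
  maximal degree-2 paths between junction/endpoint nodes become segments.
  From the pruned graph: **branching points** (degree-3 nodes; degree >= 4
  crossings are retained in the graph but excluded from bifurcation
  metrics), **mean tortuosity** (per-segment arc/chord, loops excluded),
  **mean bifurcation distance** (mean arc length of junction-to-junction
  segments), and **mean radius**.
* **Large/small split**: segments are partitioned at a mean caliber of
  20 um ("caliber" read as diameter, twice the distance-transform radius);
  tortuosity, radius, and bifurcation distance are reported per
  subnetwork. The split is an exact partition, so total arc length is
  conserved by construction.
* **Murray deviation (KS score)**: at each bifurcation the parent is the
  incident segment with the largest mean caliber (ties: longer arc, then
  lower id). Under Murray's law \(r_p^3 = r_1^3 + r_2^3\), so the
  empirical distribution of parent radius cubes matches that of summed
  daughter cubes; the score is the two-sample Kolmogorov–Smirnov statistic
  between them, in [0, 1], larger meaning greater deviation from optimal
  branching. It is reported only when at least 5 bifurcations are present
  (configurable).
* **Branching symmetry**: mean over bifurcations of smaller/larger
  daughter caliber, fixed to (0, 1] so the index is scale-free (the
  unordered daughter ratio leaves orientation undefined).

Bifurcation radii are read from the fraction of each segment's centerline
points nearest the node (default 25%), after skipping the junction-overlap
zone — points within the junction's own inscribed radius (+1 px) of the
node, where the union of the three tubes inflates the distance transform.
The near-node convention guards against taper bias on real vessels; the
overlap skip removes a systematic over-read that cubing would amplify.

Metrics that are undefined for a given eye (too few bifurcations, an empty
subnetwork) are emitted as explicit `NA`, never as zeros.

## Segmentation: optimally oriented flux

Vessels are enhanced with a 2-D optimally-oriented-flux (OOF) filter: for
each pixel and scale \(r\), the outward flux of the Gaussian-smoothed
gradient is integrated over a circle of radius \(r\), yielding a symmetric
2x2 matrix whose eigenvalues describe the local flux geometry; a bright
tube on a dark background drives the cross-sectional eigenvalue strongly
negative when \(r\) matches the vessel half-width. The per-pixel response
is the negated smaller eigenvalue (clipped at zero), maximized over an
ascending scale set (default 1–10 px, i.e. half-widths of roughly 6–60 um
at 512 px / 3 mm), with the best-responding scale recorded. Circle samples
use reflect padding (a macula-centered scan has no meaningful image
boundary), bilinear interpolation, and a sample count rounded to a
multiple of four so the response is exactly equivariant under 90-degree
rotation.

Two deliberate choices:

* **Intensity weighting (default on).** The raw eigenvalue measure also
  responds in a halo just outside the vessel wall, where circles centered
  in the background still graze the wall-gradient ridge; thresholding that
  response over-segments every vessel by ~2 px all around (Dice ~0.62
  against ground truth even at zero noise). Because OCT-A intensity *is*
  the perfusion signal, the response is multiplied by the smoothed image,
  which suppresses the halo (zero-noise Dice 0.957) and leaves scale
  selection, rotational behavior, and the zero response on constant
  images untouched. `intensity_weight = FALSE` restores the pure
  eigenvalue response.
* **Thresholding** is global Otsu on the response by default
  (parameter-free; the applied threshold is logged on the mask), with
  fixed and quantile alternatives. Deterministic cleanup removes
  components below 30 px and fills interior holes below 30 px, and is
  idempotent. The study this design follows resolved residual errors by
  manual editing; this package substitutes the deterministic cleanup so
  results are reproducible.

The scale range and the local-vs-global threshold question are genuinely
open in the source pipeline; both are exposed in the configuration with
the defaults above.

## Skeleton, radii, and graph: numerical choices

**Thinning.** Zhang–Suen thinning (which only deletes simple pixels, so
the skeleton is a subset of the mask and topology is preserved) is
followed by two cleanup passes: dissolving residual 2x2 blocks, and
removing *staircase redundancy* — non-endpoint pixels whose skeleton
neighbors form a single 8-connected component. Without the second pass,
diagonal runs keep redundant pixels whose neighbor counts mimic junctions,
and junction clusters can chain along a tube and merge two distinct
bifurcations into one spurious degree-4 node.

**Arc length.** The raw 8-connected chain-code sum (1 or sqrt(2) per
step) overestimates oblique digital curves by up to ~8% (a digital line at
angle \(t\) has chain length \(\cos t + (\sqrt2 - 1)\sin t\) per unit true
length, maximal at 22.5 deg), which would push the tortuosity of a
rasterized semicircle from \(\pi/2 \approx 1.571\) to ~1.64. Arc length is
therefore measured on a lightly smoothed (moving average, endpoints
fixed), uniformly resampled copy of the traced path. This is exact on
collinear paths — a 101-pixel straight row still measures exactly 100
steps — and within ~1% on curves; by the triangle inequality the measured
arc can never drop below the chord.

**Radii.** The local radius is the Euclidean distance from the centerline
to the nearest tissue pixel. Two quantization effects make the naive
value (EDT at the skeleton pixel, minus half a pixel) err by up to a full
pixel on thin vessels: the distance is measured to a background pixel
*center* rather than to the boundary, and the thinned skeleton can sit
half a pixel off the true centerline. The estimator therefore (1) builds
the signed distance field on a 2x bilinearly upsampled mask — along an
oblique tube the boundary staircase encodes the sub-pixel wall offset,
and interpolation recovers part of it; (2) reconstructs the ridge apex of
that field from opposing-neighbor pairs by intersecting unit-slope lines;
and (3) applies a fixed monotone calibration lookup measured once on
rasterized tubes of known radius (0.6–10 px, angles 0–90 deg, random
sub-pixel phases). Tube-mean radius error is within about +-0.3 px for
radii of 2–10 px; below ~1.3 px radius the mask genuinely cannot resolve
the width and the generator flags such segments as sub-resolution.

**Pruning** removes terminal spurs shorter than 10 um (below capillary
caliber, so no true branch can be removed), collapses short self-loops
and short parallel duplicate paths between the same node pair (junction
blobs thin into 1–2 px loops), merges the resulting degree-2 nodes, and
repeats to a fixed point, making the operation idempotent. Before
graphing, `compute_phenotypes` fills interior mask holes up to 30 px
(configurable), since hair-thin rasterization holes at junctions
otherwise corrupt the local topology.

## The synthetic angiogram generator

The generator emulates the features of a macula-centered SVC scan that
the phenotype panel measures, with every quantity known analytically:

* a binary recursive tree entering from the image edge; daughter radii
  solve \(r_p^k = r_1^k + r_2^k\) exactly at a configurable exponent
  (3 = Murray's law) with daughter ratio `symmetry` (default 0.8); root
  radius 20 um and five generations span calibers of roughly 40 down to
  9 um, matching the caliber range visible in 3 mm SVC scans;
* sinusoidal centerline tortuosity (displacement amplitude as a fraction
  of segment length, default 0.06, vanishing at segment ends so chord
  lengths are exact);
* a central vessel-free FAZ disk (300 um radius), optionally bounded by a
  circular capillary arcade with short radial spokes. The spokes fragment
  the perifoveal background the way the real capillary mesh does; without
  them the empty annulus around the arcade — not the FAZ — would be the
  largest vessel-free central region on a sparse tree;
* branching-angle jitter with floors (>= 25 deg off the parent axis,
  >= 45 deg between daughters), opposite-sign daughter sinusoid phases,
  and trimmed-chord collision checks so branches never tangentially merge
  — a generator-validity constraint that keeps the ground-truth topology
  (bifurcation count, per-segment radii) true of the rasterized image;
* rasterization by exact disk sweep (a pixel is vessel iff its center
  lies within the local radius of the centerline), and a speckle-dominated
  noise model: intensity levels, Gaussian optical blur, and unit-mean
  multiplicative gamma speckle of configurable variance. The source
  study's device noise statistics are not published; this noise model is
  the package's own and is documented as such.

The trees are sparser than a real capillary mesh (vessel densities of a
few percent rather than ~35%), contain no projection artifacts or
arteriole/venule distinction, and their segments have constant radius.
Passing recovery tests on these images therefore establishes that the
*estimators* are correct at realistic calibers and noise levels — not
that segmentation of clinical scans reaches any particular Dice.

## The cohort simulator and GEE

The cohort generator emulates the study design the statistics target: two
eyes per participant, baseline and follow-up visits with per-eye
attrition, covariates resembling a middle-aged, high-BMI, moderate/severe
OSA population, SVD outcome markers, sleep variables, and CPAP usage drawn
from a mixture so both adherence classes are populated. Any variable with
unit variance decomposes as participant component plus eye component,
with the participant share equal to `within_participant_corr` (the
fellow-eye ICC under null effects, default 0.5 — fellow eyes of the same
person are strongly but not perfectly correlated). Outcomes named in
`effect_sizes` are built as \(y = \sum_j \beta_j z_j + b + \epsilon\) on
the z-scale with total variance 1, so each \(\beta_j\) is exactly the true
standardized coefficient; follow-up phenotype change is driven by
standardized CPAP usage the same way.

Association models use generalized estimating equations with identity
link, exchangeable working correlation (fellow eyes are exchangeable
units; an independence structure is available as a sensitivity option,
under which the point estimates coincide with OLS), cluster-robust
sandwich standard errors, and Wald inference with normal quantiles. The
outcome and all continuous predictors are z-scored on the analysis sample
so coefficients are standardized; binary covariates stay 0/1 so group
contrasts remain interpretable. Rows with missing model variables are
excluded per analysis and counted, p-values are reported without
multiplicity correction (the design is exploratory), and ordinal brain
scores are carried as continuous — their upper categories are too sparse
to support ordinal models. The engine is validated three ways: exact
agreement with OLS for independent clusters, exact agreement with a dense
GLS solve at the same working correlation, and ~1e-8 agreement (betas,
robust SEs, and the exchangeable parameter) with an independent reference
implementation.

Longitudinal group comparisons use a two-tailed t-test when both groups
pass a Shapiro–Wilk normality gate at alpha = 0.05 and a Mann–Whitney U
test otherwise, reporting which test ran; the source design used both
tests without stating a selection rule, so the gate is this package's
documented choice. Both published CPAP-adherence definitions are
implemented — "at least 4 h/night on 80% of nights" and "mean usage at
least 4 h/night" — because the source design uses the former for
descriptive tables and the latter for longitudinal grouping; analyses
select one per configuration.

## Validation experiments and their tolerances

The acceptance suite (mirrored by `scripts/acceptance.R`) recomputes:

* **KS oracle**: the KS statistic agrees exactly with a brute-force
  pooled-point ECDF scan on 1,000 random tie-rich sample pairs.
* **Murray exactness**: on exact-law trees the analytic KS is zero (cube
  values are compared after rounding to 8 significant digits, since the
  cube/cube-root round trip leaves ~1-ulp noise that would otherwise flip
  ECDF ties), and the mean pipeline KS after 512-px rasterization over
  the fixed 20-tree replicate set stays at or below 0.15.
* **Murray monotonicity**: the KS score, pooled over bifurcations across
  the 20 trees per exponent, is ordered consistently with the analytic
  score across exponents {3.0, 2.6, 2.2, 1.8}. The analytic score itself
  saturates between 2.2 and 1.8 (0.267 for both: the radius-cube clusters
  have fully separated), so that pair is an analytic tie with nothing for
  the estimate to resolve; ordering is asserted across all analytically
  distinct pairs.
* **Geometry recovery** at 512 px / 3 mm: tube radius error below 0.5 px
  for widths 4–20 px; semicircle tortuosity \(\pi/2\) within 2%; the
  300-um exclusion-disk FAZ within 5% of \(\pi r^2\) (2% at 1024 px);
  branching-point counts exactly matching generator truth.
* **Segmentation**: Dice >= 0.95 at zero noise, non-increasing across
  five increasing speckle variances.
* **GEE**: a true standardized beta of 0.40 recovered within +-0.05 as
  the mean of 200 replicates (500 participants, two eyes, ICC 0.5), with
  null 95% CI coverage between 90% and 99%.
* **Conservation and determinism**: the 20-um split partitions segments
  with arc length conserved to machine precision, and two pipeline runs
  with the same configuration and seed produce byte-identical phenotype
  CSVs.
* **Study-scale smoke test**: a 43-participant cohort with ~37 right-eye
  follow-ups runs the complete association suite and emits a
  forest-plot-ready coefficient table without error.

Problem sizes (20 trees per exponent at 512 px, 200 GEE replicates at
n = 500, six speckle levels at 512 px) were chosen as the smallest designs
at which each property is measured stably; the tree experiments use a
fixed replicate set because the trees are the experimental material, while
scan noise, cohort draws, and fixture placements follow the session seed.

## Known limitations

* Radii below ~1.3 px are not resolvable from a binary mask; the
  corresponding generator segments are flagged sub-resolution, and
  bifurcations among such vessels dominate the residual Murray-KS noise.
* Degree-4+ nodes are treated as crossings and excluded from bifurcation
  metrics; no attempt is made to disambiguate true crossings from closely
  spaced bifurcations.
* The tortuosity mean is unweighted per segment (not length-weighted);
  the source design does not state which was used.
* The angiogram simulator does not model projection artifacts,
  decorrelation tails, vessel taper within a segment, or the capillary
  mesh's space-filling density; conclusions about clinical segmentation
  accuracy cannot be drawn from it.
* GEE inference uses normal quantiles; with very few clusters (< ~20)
  robust standard errors are known to be anti-conservative, which matters
  for the n = 43 study-scale runs and is why they are smoke tests rather
  than calibration claims.
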