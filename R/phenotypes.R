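# The retinal phenotype panel: regional vessel densities, FAZ area,
# tortuosity, branching points, bifurcation distance, mean radius,
# Murray-deviation KS score and branching symmetry, with large/small
# variants from the 20 um caliber split.

#' Concentric analysis regions for a macular scan
#'
#' Image-centered foveal circle, parafoveal annulus, and the central
#' search disk used for FAZ detection, following the ETDRS-style
#' convention for 3 mm scans (foveal circle 1 mm diameter, parafoveal
#' ring from the foveal edge out to 3 mm).
#'
#' @param dims integer(2) image dimensions (rows, cols).
#' @param scale_um_per_px physical pixel size, um.
#' @param foveal_diameter_mm diameter of the foveal circle.
#' @param parafoveal_outer_diameter_mm outer diameter of the parafoveal
#'   ring (its inner diameter is the foveal diameter, so the two regions
#'   are disjoint by construction).
#' @param faz_search_diameter_mm diameter of the central FAZ search disk.
#' @return A `region_masks` list of logical matrices `foveal_circle`,
#'   `parafoveal_ring`, `central_region`, plus the geometry parameters.
#' @export
make_region_masks <- function(dims, scale_um_per_px,
                              foveal_diameter_mm = 1,
                              parafoveal_outer_diameter_mm = 3,
                              faz_search_diameter_mm = 1.5) {
  stopifnot(length(dims) == 2, scale_um_per_px > 0,
            foveal_diameter_mm > 0,
            parafoveal_outer_diameter_mm > foveal_diameter_mm)
  fov_um <- dims[2] * scale_um_per_px
  if (parafoveal_outer_diameter_mm * 1000 > fov_um + 1e-6 ||
      faz_search_diameter_mm * 1000 > fov_um + 1e-6)
    stop("region geometry exceeds the image field of view")
  cx <- dims[2] / 2 + 0.5
  cy <- dims[1] / 2 + 0.5
  d_px <- sqrt(outer(((1:dims[1]) - cy)^2, ((1:dims[2]) - cx)^2, "+"))
  d_um <- d_px * scale_um_per_px
  r_fov <- foveal_diameter_mm * 500
  r_para <- parafoveal_outer_diameter_mm * 500
  r_cent <- faz_search_diameter_mm * 500
  structure(list(foveal_circle = d_um <= r_fov,
                 parafoveal_ring = d_um > r_fov & d_um <= r_para,
                 central_region = d_um <= r_cent,
                 center_px = c(x = cx, y = cy),
                 foveal_diameter_mm = foveal_diameter_mm,
                 parafoveal_outer_diameter_mm = parafoveal_outer_diameter_mm,
                 faz_search_diameter_mm = faz_search_diameter_mm,
                 scale_um_per_px = scale_um_per_px),
            class = "region_masks")
}

#' Vessel density within a region
#'
#' Ratio of vessel (white) pixels over the total pixels of the region of
#' interest: an exact rational count/count.
#'
#' @param mask a [vessel_mask()] (or logical matrix).
#' @param region logical matrix of the same dimensions.
#' @return Fraction in \[0, 1\].
#' @export
vessel_density <- function(mask, region) {
  m <- unclass(mask) == TRUE
  stopifnot(all(dim(m) == dim(region)))
  n_region <- sum(region)
  if (n_region == 0) stop("empty region of interest")
  sum(m & region) / n_region
}

#' Detect the foveal avascular zone
#'
#' The FAZ is the largest vessel-free connected area in the central
#' region of the scan: connected components (4-connectivity, the dual of
#' the 8-connected vasculature) of the background restricted to the
#' central search disk, keeping the largest by pixel area. Area is
#' converted to mm^2 via the squared pixel scale.
#'
#' @param mask a [vessel_mask()].
#' @param central_region logical matrix of the same dimensions (the
#'   `central_region` of [make_region_masks()]).
#' @return List with `faz_area_mm2`, `faz_mask` (logical matrix of the
#'   selected component) and `faz_area_px`.
#' @export
detect_faz <- function(mask, central_region) {
  m <- unclass(mask) == TRUE
  stopifnot(all(dim(m) == dim(central_region)))
  bg <- (!m) & central_region
  if (!any(bg))
    stop("no vessel-free pixels intersect the central region")
  lab <- EBImage::bwlabel(t(bg))
  sz <- tabulate(lab[lab > 0])
  best <- which.max(sz)
  comp <- t(matrix(lab == best, nrow(lab), ncol(lab)))
  scale <- mask_scale(mask)
  list(faz_area_mm2 = sz[best] * (scale / 1000)^2,
       faz_mask = comp,
       faz_area_px = sz[best])
}

#' Mean vessel tortuosity of a graph
#'
#' Mean over segments of arc length divided by endpoint chord length
#' (1 for a straight vessel). Closed loops (chord = 0) are excluded and
#' counted in the `n_excluded_loops` attribute.
#'
#' @param graph a `vessel_graph`.
#' @return Mean tortuosity (>= 1), or an error if no segment has a
#'   positive chord.
#' @export
mean_tortuosity <- function(graph) {
  segs <- graph$segments
  ok <- segs$chord_um > 0
  if (!any(ok)) stop("no segments with positive chord length")
  out <- mean(segs$arc_um[ok] / segs$chord_um[ok])
  attr(out, "n_excluded_loops") <- sum(!ok)
  out
}

#' Count branching points
#'
#' Branching points are nodes of degree three in the (pruned) vessel
#' graph; degree >= 4 nodes (crossings) are not counted.
#'
#' @param graph a `vessel_graph`.
#' @return Integer count.
#' @export
branching_points <- function(graph) {
  sum(graph$nodes$degree == 3L)
}

#' Mean bifurcation distance
#'
#' Mean vessel (arc) length of segments that connect two branching
#' points; terminal segments are excluded. Returns `NA` when the graph
#' has no junction-to-junction segment (recorded, not an error).
#'
#' @param graph a `vessel_graph`.
#' @return Mean arc length in um, or `NA_real_`.
#' @export
mean_bifurcation_distance <- function(graph) {
  if (nrow(graph$segments) == 0) return(NA_real_)
  degv <- deg_by_id(graph$segments, max(graph$nodes$id, 1L))
  jj <- degv[graph$segments$from] == 3 & degv[graph$segments$to] == 3 &
    graph$segments$from != graph$segments$to
  if (!any(jj)) return(NA_real_)
  mean(graph$segments$arc_um[jj])
}

# Two-sample Kolmogorov-Smirnov statistic: sup over the pooled sample
# points of the absolute ECDF difference. Handles ties exactly.
ks_statistic <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  pts <- sort(unique(c(x, y)))
  fx <- ecdf(x)(pts)
  fy <- ecdf(y)(pts)
  max(abs(fx - fy))
}

#' Murray's-law deviation (KS score)
#'
#' In an optimally branching network, Murray's law
#' \eqn{r_p^3 = r_1^3 + r_2^3} holds at every bifurcation, so the
#' distribution of parent radius cubes matches the distribution of
#' summed daughter radius cubes. The KS score is the two-sample
#' Kolmogorov-Smirnov statistic between the empirical distributions of
#' \eqn{\{r_p^3\}} and \eqn{\{r_1^3 + r_2^3\}} over the graph's
#' bifurcations; a higher score signifies a greater deviation from
#' Murray's law.
#'
#' @param graph a `vessel_graph`, or a bifurcation table from
#'   [bifurcation_table()].
#' @param min_bifurcations minimum number of bifurcations required; with
#'   fewer the score is `NA` (logged via attribute `n_bifurcations`).
#' @param near_frac passed to [bifurcation_table()].
#' @return KS score in \[0, 1\], or `NA_real_`.
#' @export
murray_ks_score <- function(graph, min_bifurcations = 5, near_frac = 0.25) {
  bt <- if (inherits(graph, "vessel_graph"))
    bifurcation_table(graph, near_frac) else graph
  out <- if (nrow(bt) < min_bifurcations) NA_real_
  else ks_statistic(bt$parent_radius_um^3,
                    bt$d1_radius_um^3 + bt$d2_radius_um^3)
  attr(out, "n_bifurcations") <- nrow(bt)
  out
}

#' Mean branching symmetry ratio
#'
#' Mean over bifurcations of the smaller daughter caliber divided by the
#' larger one, a scale-free index in (0, 1] of how evenly caliber is
#' shared after a bifurcation.
#'
#' @inheritParams murray_ks_score
#' @return Mean ratio, or `NA_real_` if the graph has no bifurcation.
#' @export
mean_symmetry_ratio <- function(graph, near_frac = 0.25) {
  bt <- if (inherits(graph, "vessel_graph"))
    bifurcation_table(graph, near_frac) else graph
  if (nrow(bt) == 0) return(NA_real_)
  mean(bt$d2_radius_um / bt$d1_radius_um)
}

#' Mean vessel radius of a graph
#'
#' Mean of the per-centerline-point radius over all segments of the
#' (sub)network, in um.
#'
#' @param graph a `vessel_graph`.
#' @return Mean radius, or `NA_real_` for an empty graph.
#' @export
mean_radius <- function(graph) {
  if (nrow(graph$segments) == 0) return(NA_real_)
  mean(unlist(graph$segments$radius_um))
}

#' Phenotype pipeline configuration
#'
#' @param foveal_diameter_mm,parafoveal_outer_diameter_mm,faz_search_diameter_mm
#'   region geometry ([make_region_masks()]).
#' @param caliber_threshold_um large/small caliber cut, um.
#' @param prune_um spur-pruning threshold, um.
#' @param min_bifurcations minimum bifurcations for the KS score.
#' @param near_frac near-node fraction for bifurcation radii.
#' @param fill_holes_px mask hygiene before graphing: interior background
#'   holes up to this area (px) are filled, so that hair-thin rasterization
#'   holes at junctions do not corrupt the centerline topology (0 disables).
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(foveal_diameter_mm = 1,
                             parafoveal_outer_diameter_mm = 3,
                             faz_search_diameter_mm = 1.5,
                             caliber_threshold_um = 20,
                             prune_um = 10,
                             min_bifurcations = 5,
                             near_frac = 0.25,
                             fill_holes_px = 30) {
  structure(list(foveal_diameter_mm = foveal_diameter_mm,
                 parafoveal_outer_diameter_mm = parafoveal_outer_diameter_mm,
                 faz_search_diameter_mm = faz_search_diameter_mm,
                 caliber_threshold_um = caliber_threshold_um,
                 prune_um = prune_um,
                 min_bifurcations = min_bifurcations,
                 near_frac = near_frac,
                 fill_holes_px = fill_holes_px),
            class = "phenotype_config")
}

#' Compute the full retinal phenotype panel from a mask
#'
#' Runs region construction, FAZ detection, graph construction with
#' pruning, the 20 um caliber split, and every graph metric. Metrics that
#' are undefined for a given mask (for example the KS score with too few
#' bifurcations, or small-vessel metrics when the small network is
#' empty) are emitted as `NA`, never as zeros, and never abort the
#' record. Deterministic: the same mask and configuration yield an
#' identical record.
#'
#' @param mask a [vessel_mask()] with a physical scale.
#' @param config a [phenotype_config()].
#' @return One-row tibble: `parafoveal_vd`, `foveal_vd`,
#'   `branching_points`, `faz_area_mm2`, `tortuosity_large`,
#'   `tortuosity_small`, `radius_large_um`, `radius_small_um`,
#'   `ks_score`, `symmetry_ratio`, `bifurcation_distance_large_um`,
#'   `bifurcation_distance_small_um`, plus bookkeeping columns
#'   `n_bifurcations` and `vessel_px`. The FAZ component is attached as
#'   attribute `faz_mask` for QC overlays.
#' @export
compute_phenotypes <- function(mask, config = phenotype_config()) {
  scale <- mask_scale(mask)
  regions <- make_region_masks(dim(mask), scale,
                               config$foveal_diameter_mm,
                               config$parafoveal_outer_diameter_mm,
                               config$faz_search_diameter_mm)
  para_vd <- vessel_density(mask, regions$parafoveal_ring)
  fov_vd <- vessel_density(mask, regions$foveal_circle)
  faz <- tryCatch(detect_faz(mask, regions$central_region),
                  error = function(e) list(faz_area_mm2 = NA_real_,
                                           faz_mask = NULL))
  safe <- function(expr) tryCatch(as.numeric(expr)[1],
                                  error = function(e) NA_real_)
  if (any(mask)) {
    gmask <- if (config$fill_holes_px > 0)
      clean_mask(mask, min_component_px = 0,
                 fill_holes_px = config$fill_holes_px) else mask
    g <- mask_to_graph(gmask, prune_um = config$prune_um)
    halves <- split_by_caliber(g, config$caliber_threshold_um)
    bt <- bifurcation_table(g, config$near_frac)
    rec <- tibble::tibble(
      parafoveal_vd = para_vd,
      foveal_vd = fov_vd,
      branching_points = branching_points(g),
      faz_area_mm2 = faz$faz_area_mm2,
      tortuosity_large = safe(mean_tortuosity(halves$large)),
      tortuosity_small = safe(mean_tortuosity(halves$small)),
      radius_large_um = safe(mean_radius(halves$large)),
      radius_small_um = safe(mean_radius(halves$small)),
      ks_score = safe(murray_ks_score(bt, config$min_bifurcations)),
      symmetry_ratio = safe(mean_symmetry_ratio(bt)),
      bifurcation_distance_large_um = safe(mean_bifurcation_distance(halves$large)),
      bifurcation_distance_small_um = safe(mean_bifurcation_distance(halves$small)),
      n_bifurcations = nrow(bt),
      vessel_px = sum(mask))
  } else {
    rec <- tibble::tibble(
      parafoveal_vd = para_vd, foveal_vd = fov_vd,
      branching_points = 0L, faz_area_mm2 = faz$faz_area_mm2,
      tortuosity_large = NA_real_, tortuosity_small = NA_real_,
      radius_large_um = NA_real_, radius_small_um = NA_real_,
      ks_score = NA_real_, symmetry_ratio = NA_real_,
      bifurcation_distance_large_um = NA_real_,
      bifurcation_distance_small_um = NA_real_,
      n_bifurcations = 0L, vessel_px = 0L)
  }
  attr(rec, "faz_mask") <- faz$faz_mask
  rec
}
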