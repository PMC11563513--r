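#' Specification of a synthetic vascular tree
#'
#' Parameters of a binary bifurcating tree that emulates the superficial
#' vascular complex of a macula-centered 3 mm x 3 mm OCT-A scan: a trunk
#' entering from the image edge, recursive bifurcations whose daughter
#' radii obey a generalized Murray law
#' \eqn{r_p^k = r_1^k + r_2^k} with \eqn{r_2/r_1} equal to `symmetry`,
#' sinusoidal centerline tortuosity, and a central vessel-free disk
#' (the foveal avascular zone, FAZ). Optionally the FAZ is bounded by a
#' circular capillary arcade (`faz_ring`) with short radial capillaries
#' (`n_spokes`) that fragment the perifoveal background the way a real
#' capillary mesh does.
#'
#' All geometry is generated in physical micrometre coordinates on a
#' `fov_um` x `fov_um` canvas (origin top-left, x right, y down) and is
#' independent of any later rasterization resolution.
#'
#' @param root_position_um numeric(2), (x, y) of the trunk origin in um.
#' @param root_dir_deg initial trunk direction in degrees (0 = +x, 90 = +y).
#' @param root_radius_um trunk radius in um (> 0).
#' @param branch_levels number of segment generations (>= 1); a tree with
#'   `L` levels has `2^L - 1` segments and `2^(L-1) - 1` bifurcations.
#' @param murray_exponent exponent `k` of the radius law; 3 is the exact
#'   Murray law.
#' @param symmetry target daughter radius ratio `r2/r1` in (0, 1].
#' @param tortuosity_amplitude sinusoidal displacement amplitude as a
#'   fraction of segment length (0 = straight segments).
#' @param sinusoid_periods number of full sine periods per segment.
#' @param faz_radius_um radius of the central vessel-free disk, um.
#' @param faz_ring logical; draw a circular arcade bounding the FAZ.
#' @param ring_radius_um vessel radius of the arcade, um.
#' @param n_spokes number of radial capillaries attached to the arcade
#'   (0 disables them).
#' @param spoke_radius_um vessel radius of the spokes, um.
#' @param spoke_outer_um outer radial extent of the spokes, um from center.
#' @param branch_angle_deg full opening angle between the two daughters.
#' @param angle_jitter_deg s.d. of the Gaussian jitter added to each
#'   daughter direction.
#' @param initial_length_um trunk segment length, um.
#' @param length_decay per-level multiplicative decay of segment length.
#' @param fov_um canvas side length, um (3000 for a 3 mm scan).
#' @param seed integer seed; all randomness in [generate_tree()] flows
#'   through this one seed.
#' @return An object of class `tree_spec` (a validated list).
#' @seealso [generate_tree()], [rasterize_tree()]
#' @export
tree_spec <- function(root_position_um = c(150, 1500),
                      root_dir_deg = 0,
                      root_radius_um = 20,
                      branch_levels = 5L,
                      murray_exponent = 3,
                      symmetry = 0.8,
                      tortuosity_amplitude = 0.06,
                      sinusoid_periods = 1,
                      faz_radius_um = 300,
                      faz_ring = TRUE,
                      ring_radius_um = 8,
                      n_spokes = 12L,
                      spoke_radius_um = 6,
                      spoke_outer_um = 800,
                      branch_angle_deg = 75,
                      angle_jitter_deg = 10,
                      initial_length_um = 700,
                      length_decay = 0.65,
                      fov_um = 3000,
                      seed = 1L) {
  stopifnot(length(root_position_um) == 2, all(is.finite(root_position_um)),
            root_radius_um > 0, branch_levels >= 1,
            murray_exponent > 0, symmetry > 0, symmetry <= 1,
            tortuosity_amplitude >= 0, faz_radius_um >= 0,
            initial_length_um > 0, length_decay > 0, fov_um > 0)
  spec <- list(root_position_um = as.numeric(root_position_um),
               root_dir_deg = root_dir_deg,
               root_radius_um = root_radius_um,
               branch_levels = as.integer(branch_levels),
               murray_exponent = murray_exponent,
               symmetry = symmetry,
               tortuosity_amplitude = tortuosity_amplitude,
               sinusoid_periods = sinusoid_periods,
               faz_radius_um = faz_radius_um,
               faz_ring = isTRUE(faz_ring),
               ring_radius_um = ring_radius_um,
               n_spokes = as.integer(n_spokes),
               spoke_radius_um = spoke_radius_um,
               spoke_outer_um = spoke_outer_um,
               branch_angle_deg = branch_angle_deg,
               angle_jitter_deg = angle_jitter_deg,
               initial_length_um = initial_length_um,
               length_decay = length_decay,
               fov_um = fov_um,
               seed = as.integer(seed))
  class(spec) <- "tree_spec"
  spec
}

# Daughter radii under the generalized Murray law: r_p^k = r1^k + r2^k
# with r2/r1 = symmetry. Solved exactly so generated bifurcations satisfy
# the law to machine precision.
murray_daughters <- function(parent_radius, exponent, symmetry) {
  r1 <- parent_radius / (1 + symmetry^exponent)^(1 / exponent)
  c(r1, symmetry * r1)
}

# Sinusoidally displaced centerline from p0 towards p0 + L*dir.
# Displacement is perpendicular to the chord, amplitude*L*sin(2*pi*k*t),
# which vanishes at both ends so the chord length equals L exactly.
sinusoid_centerline <- function(p0, dir, length_um, amplitude, periods,
                                spacing_um = 2) {
  n <- max(8L, ceiling(length_um / spacing_um) + 1L)
  t <- seq(0, 1, length.out = n)
  perp <- c(-dir[2], dir[1])
  off <- amplitude * length_um * sin(2 * pi * periods * t)
  cbind(p0[1] + t * length_um * dir[1] + off * perp[1],
        p0[2] + t * length_um * dir[2] + off * perp[2])
}

# Minimum distance between two segments p0-p1 and q0-q1 (2-D).
dist_segment_segment <- function(p0, p1, q0, q1) {
  # if they intersect the distance is zero
  d1 <- p1 - p0; d2 <- q1 - q0
  cross <- function(a, b) a[1] * b[2] - a[2] * b[1]
  denom <- cross(d1, d2)
  if (abs(denom) > 1e-12) {
    t <- cross(q0 - p0, d2) / denom
    u <- cross(q0 - p0, d1) / denom
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1) return(0)
  }
  min(dist_point_segment(p0, q0, q1), dist_point_segment(p1, q0, q1),
      dist_point_segment(q0, p0, p1), dist_point_segment(q1, p0, p1))
}

# Does the straight chord p0 -> p0 + L*dir come within `clearance` of
# `center`, leave the canvas margin, or collide with an already-placed
# segment? Segments sharing the candidate's start point (the parent and
# earlier siblings) are compared against their trimmed chords (the part
# away from the shared junction), so a daughter can neither double back
# onto its parent nor be steered onto a sibling, while the legitimate
# contact at the junction itself is not flagged.
chord_violates <- function(p0, dir, length_um, center, clearance,
                           fov_um, margin_um, placed, self_pad) {
  p1 <- p0 + length_um * dir
  if (dist_point_segment(center, p0, p1) < clearance) return(TRUE)
  if (any(p1 < margin_um) || any(p1 > fov_um - margin_um)) return(TRUE)
  for (s in placed) {
    q0 <- s$p0; q1 <- s$p1; pad <- s$pad + self_pad
    if (sum((q0 - p0)^2) < 1e-12) {        # sibling: trim its start
      q0 <- s$p0 + 0.35 * (s$p1 - s$p0)
      pad <- 0.5 * pad
    } else if (sum((q1 - p0)^2) < 1e-12) { # parent: trim its end
      q1 <- s$p0 + 0.65 * (s$p1 - s$p0)
      pad <- 0.5 * pad
    }
    if (dist_segment_segment(p0, p1, q0, q1) < pad)
      return(TRUE)
  }
  FALSE
}

# Rotate a proposed direction in alternating +/- 10 degree steps until the
# segment avoids the FAZ disk, stays on canvas, and does not collide with
# previously placed branches. Errors if no rotation works: the tree would
# exceed the canvas and is never silently cropped.
steer_clear <- function(p0, dir, length_um, center, clearance,
                        fov_um, margin_um, placed, self_pad) {
  if (!chord_violates(p0, dir, length_um, center, clearance, fov_um,
                      margin_um, placed, self_pad))
    return(dir)
  for (step_deg in seq(10, 180, by = 10)) {
    for (sgn in c(1, -1)) {
      cand <- rotate2(dir, sgn * step_deg * pi / 180)
      if (!chord_violates(p0, cand, length_um, center, clearance,
                          fov_um, margin_um, placed, self_pad))
        return(cand)
    }
  }
  stop("infeasible tree geometry: a segment of length ", round(length_um),
       " um cannot be placed inside the canvas without entering the FAZ ",
       "or crossing an existing branch; reduce initial_length_um or ",
       "branch_levels")
}

#' Generate a synthetic vascular tree with analytic ground truth
#'
#' Builds the binary bifurcating tree described by a [tree_spec()]:
#' deterministic for a fixed seed, every bifurcation satisfies
#' \eqn{r_p^k = r_1^k + r_2^k} exactly, centerlines carry the configured
#' sinusoidal tortuosity, and no vessel enters the central FAZ disk.
#' Infeasible geometry (a segment that cannot be placed on the canvas)
#' raises an error rather than being cropped.
#'
#' @param spec a [tree_spec()].
#' @return A `vessel_tree`: list with `segments` (each a list with `id`,
#'   `level`, `parent`, `points` (n x 2 um), `radius_um`), optional `ring`
#'   and `spokes` geometry, the `spec`, and `ground_truth` containing
#'   per-segment arc/chord lengths and radii, per-bifurcation
#'   parent/daughter radii, the analytic FAZ area in mm^2, and the
#'   bifurcation count.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  withr::with_seed(spec$seed, generate_tree_impl(spec))
}

generate_tree_impl <- function(spec) {
  center <- c(spec$fov_um / 2, spec$fov_um / 2)
  margin <- 30
  segments <- list()
  bifurcations <- list()
  next_id <- 1L

  placed <- list()   # chords with clearance pads, for collision avoidance

  grow <- function(p0, dir, radius, level, length_um, parent_id,
                   amp_sign = 1) {
    clearance <- spec$faz_radius_um + radius +
      spec$tortuosity_amplitude * length_um + 10
    self_pad <- radius + spec$tortuosity_amplitude * length_um + 5
    dir <- steer_clear(p0, dir, length_um, center, clearance,
                       spec$fov_um, margin, placed, self_pad)
    pts <- sinusoid_centerline(p0, dir, length_um,
                               amp_sign * spec$tortuosity_amplitude,
                               spec$sinusoid_periods)
    placed[[length(placed) + 1L]] <<- list(p0 = p0,
                                           p1 = p0 + length_um * dir,
                                           pad = self_pad)
    id <- next_id; next_id <<- next_id + 1L
    segments[[id]] <<- list(id = id, level = level, parent = parent_id,
                            points = pts, radius_um = radius)
    if (level < spec$branch_levels) {
      dr <- murray_daughters(radius, spec$murray_exponent, spec$symmetry)
      bifurcations[[length(bifurcations) + 1L]] <<- list(
        segment = id, parent_radius_um = radius,
        daughter_radii_um = dr)
      half <- spec$branch_angle_deg / 2
      j1 <- rnorm(1, 0, spec$angle_jitter_deg)
      j2 <- rnorm(1, 0, spec$angle_jitter_deg)
      # floor the daughter angles (>= 25 deg off the parent axis, >= 45 deg
      # between daughters) so jitter cannot collapse the junction into a
      # tangential overlap that would corrupt the ground-truth topology
      a1 <- min(max(half + j1, 25), 85)
      a2 <- max(min(-half + j2, -25), -85)
      if (a1 - a2 < 45) {
        mid <- (a1 + a2) / 2
        a1 <- mid + 22.5; a2 <- mid - 22.5
      }
      p1 <- pts[nrow(pts), ]
      len2 <- length_um * spec$length_decay
      # each daughter's sinusoid is pushed away from the bisector, so the
      # two tubes separate cleanly beyond the junction blob
      grow(p1, rotate2(dir, a1 * pi / 180), dr[1], level + 1L, len2, id,
           amp_sign = 1)
      grow(p1, rotate2(dir, a2 * pi / 180), dr[2], level + 1L, len2, id,
           amp_sign = -1)
    }
    invisible(id)
  }

  dir0 <- c(cos(spec$root_dir_deg * pi / 180),
            sin(spec$root_dir_deg * pi / 180))
  grow(spec$root_position_um, dir0, spec$root_radius_um, 1L,
       spec$initial_length_um, NA_integer_)

  ring <- NULL
  spokes <- list()
  if (spec$faz_ring) {
    ring_center_r <- spec$faz_radius_um + spec$ring_radius_um + 2
    th <- seq(0, 2 * pi, length.out = max(64L, ceiling(pi * ring_center_r)))
    ring <- list(points = cbind(center[1] + ring_center_r * cos(th),
                                center[2] + ring_center_r * sin(th)),
                 radius_um = spec$ring_radius_um)
    if (spec$n_spokes > 0) {
      ang <- seq(0, 2 * pi, length.out = spec$n_spokes + 1L)[-1] +
        rnorm(spec$n_spokes, 0, 0.05)
      for (a in ang) {
        u <- c(cos(a), sin(a))
        spokes[[length(spokes) + 1L]] <- list(
          points = rbind(center + ring_center_r * u,
                         center + spec$spoke_outer_um * u),
          radius_um = spec$spoke_radius_um)
      }
    }
  }

  seg_gt <- do.call(rbind, lapply(segments, function(s) {
    data.frame(id = s$id, level = s$level,
               radius_um = s$radius_um,
               arc_um = polyline_length(s$points),
               chord_um = sqrt(sum((s$points[nrow(s$points), ] -
                                      s$points[1, ])^2)))
  }))
  bif_gt <- if (length(bifurcations)) do.call(rbind, lapply(bifurcations,
    function(b) data.frame(segment = b$segment,
                           parent_radius_um = b$parent_radius_um,
                           d1_radius_um = b$daughter_radii_um[1],
                           d2_radius_um = b$daughter_radii_um[2])))
    else data.frame(segment = integer(), parent_radius_um = numeric(),
                    d1_radius_um = numeric(), d2_radius_um = numeric())

  internal <- seg_gt$level < spec$branch_levels & seg_gt$level > 1L
  structure(list(
    segments = segments, ring = ring, spokes = spokes, spec = spec,
    ground_truth = list(
      segments = seg_gt,
      bifurcations = bif_gt,
      n_bifurcations = nrow(bif_gt),
      mean_internal_arc_um = if (any(internal)) mean(seg_gt$arc_um[internal])
                             else NA_real_,
      faz_area_mm2 = pi * (spec$faz_radius_um / 1000)^2,
      mean_symmetry = if (nrow(bif_gt)) mean(bif_gt$d2_radius_um /
                                               bif_gt$d1_radius_um)
                      else NA_real_)),
    class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("<vessel_tree>", length(x$segments), "segments,",
      x$ground_truth$n_bifurcations, "bifurcations,",
      "FAZ", format(x$ground_truth$faz_area_mm2, digits = 3), "mm^2\n")
  invisible(x)
}

#' Rasterize a vascular tree into a binary mask
#'
#' Sweeps a disk of each segment's local radius along its centerline on a
#' square pixel grid: a pixel is vessel iff its center lies within the
#' local radius of the centerline. The physical scale
#' `fov_mm * 1000 / image_size_px` um/px is recorded on the mask. Segments
#' whose radius falls below one pixel at the chosen scale are flagged in
#' the ground truth as sub-resolution (a warning record, not an error).
#'
#' @param tree a `vessel_tree` from [generate_tree()].
#' @param image_size_px side length of the square image, px.
#' @param fov_mm physical field of view, mm.
#' @return A `vessel_mask` (logical matrix with `scale_um_per_px`
#'   attribute) with attribute `ground_truth`: the tree's ground truth
#'   plus realized `vessel_pixel_count`, the scale, and the ids of
#'   sub-resolution segments.
#' @export
rasterize_tree <- function(tree, image_size_px = 512L, fov_mm = 3) {
  stopifnot(inherits(tree, "vessel_tree"), fov_mm > 0, image_size_px >= 8)
  scale <- fov_mm * 1000 / image_size_px
  m <- matrix(FALSE, image_size_px, image_size_px)
  sub_res <- integer()
  for (s in tree$segments) {
    r_px <- s$radius_um / scale
    if (r_px < 1) sub_res <- c(sub_res, s$id)
    m <- paint_tube(m, s$points / scale, r_px)
  }
  if (!is.null(tree$ring))
    m <- paint_tube(m, tree$ring$points / scale, tree$ring$radius_um / scale)
  for (sp in tree$spokes)
    m <- paint_tube(m, sp$points / scale, sp$radius_um / scale)
  gt <- tree$ground_truth
  gt$scale_um_per_px <- scale
  gt$vessel_pixel_count <- sum(m)
  gt$sub_resolution_segments <- sub_res
  vessel_mask(m, scale, ground_truth = gt)
}

#' Rasterize a single tube (arbitrary centerline) into a binary mask
#'
#' Convenience constructor for geometric fixtures (bars, rings,
#' semicircular arcs) measured in physical units.
#'
#' @param points_um n x 2 centerline, um coordinates (x right, y down).
#' @param radius_um tube radius, um.
#' @param image_size_px,fov_mm grid geometry as in [rasterize_tree()].
#' @return A `vessel_mask`.
#' @export
rasterize_tube <- function(points_um, radius_um, image_size_px = 512L,
                           fov_mm = 3) {
  scale <- fov_mm * 1000 / image_size_px
  m <- matrix(FALSE, image_size_px, image_size_px)
  m <- paint_tube(m, points_um / scale, radius_um / scale)
  vessel_mask(m, scale)
}

#' Binary vessel mask
#'
#' A logical pixel grid plus its physical scale in um per pixel; the
#' common currency between the segmentation, graph, and phenotype stages.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param scale_um_per_px physical pixel size, um.
#' @param ground_truth optional generator ground truth carried along for
#'   validation.
#' @return Object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, scale_um_per_px, ground_truth = NULL) {
  stopifnot(is.matrix(mask), scale_um_per_px > 0)
  storage.mode(mask) <- "logical"
  structure(mask, scale_um_per_px = scale_um_per_px,
            ground_truth = ground_truth, class = c("vessel_mask", "matrix"))
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat("<vessel_mask>", nrow(x), "x", ncol(x), "px,",
      format(attr(x, "scale_um_per_px"), digits = 4), "um/px,",
      sum(x), "vessel px\n")
  invisible(x)
}

mask_scale <- function(mask) {
  s <- attr(mask, "scale_um_per_px")
  if (is.null(s)) stop("mask carries no scale_um_per_px attribute")
  s
}

#' Render a noisy angiogram from a binary mask
#'
#' Produces a grayscale en-face image in \[0, 1\]: vessel and background
#' intensities, Gaussian optical blur, then multiplicative speckle with a
#' unit-mean gamma multiplier of the configured variance (the OCT-A
#' decorrelation signal is speckle-dominated). Deterministic for a fixed
#' seed. The study scanner's noise statistics are not published; these
#' parameters are the package's own documented model.
#'
#' @param mask a `vessel_mask`.
#' @param vessel_intensity,background_intensity mean intensities in \[0, 1\].
#' @param speckle_var variance of the unit-mean multiplicative speckle
#'   multiplier (0 disables speckle).
#' @param blur_sigma_px Gaussian blur s.d. in px (0 disables blur).
#' @param seed integer seed.
#' @param fov_mm field of view, mm.
#' @return An [angiogram_image()].
#' @export
render_angiogram <- function(mask, vessel_intensity = 0.75,
                             background_intensity = 0.15,
                             speckle_var = 0.1, blur_sigma_px = 1,
                             seed = 1L, fov_mm = 3) {
  stopifnot(vessel_intensity >= 0, vessel_intensity <= 1,
            background_intensity >= 0, background_intensity <= 1,
            speckle_var >= 0, blur_sigma_px >= 0)
  img <- background_intensity +
    (vessel_intensity - background_intensity) * (mask * 1)
  img <- gaussian_blur(img, blur_sigma_px)
  if (speckle_var > 0) {
    img <- withr::with_seed(as.integer(seed), {
      shp <- 1 / speckle_var
      img * matrix(rgamma(length(img), shape = shp, rate = shp),
                   nrow(img), ncol(img))
    })
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  angiogram_image(img, fov_mm = fov_mm)
}

#' Grayscale en-face angiogram with physical scale
#'
#' @param pixels numeric matrix in \[0, 1\] (square).
#' @param fov_mm physical width of the field of view, mm.
#' @param quality_index optional device-reported quality score.
#' @return Object of class `angiogram_image` with derived
#'   `scale_um_per_px = fov_mm * 1000 / ncol(pixels)`.
#' @export
angiogram_image <- function(pixels, fov_mm = 3, quality_index = NA_real_) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels),
            all(is.finite(pixels)), fov_mm > 0)
  structure(list(pixels = pixels, fov_mm = fov_mm,
                 scale_um_per_px = fov_mm * 1000 / ncol(pixels),
                 quality_index = quality_index),
            class = "angiogram_image")
}

#' @export
print.angiogram_image <- function(x, ...) {
  cat("<angiogram_image>", nrow(x$pixels), "x", ncol(x$pixels), "px,",
      x$fov_mm, "mm fov,", format(x$scale_um_per_px, digits = 4), "um/px\n")
  invisible(x)
}
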