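# Shared fixture builders and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

# Straight tube through the image center at a given angle, physical units.
straight_tube_mask <- function(radius_px, angle_deg, image_size_px = 256,
                               fov_mm = 3, offset_um = c(0, 0),
                               half_length_um = 600) {
  scale <- fov_mm * 1000 / image_size_px
  a <- angle_deg * pi / 180
  ctr <- c(fov_mm * 500, fov_mm * 500) + offset_um
  pts <- rbind(ctr - half_length_um * c(cos(a), sin(a)),
               ctr + half_length_um * c(cos(a), sin(a)))
  list(mask = rasterize_tube(pts, radius_px * scale, image_size_px, fov_mm),
       ends = pts, scale = scale)
}

# Mean recovered radius (px) over tube interior, excluding both ends.
tube_mean_radius_px <- function(fix, r_px) {
  sk <- radius_from_distance(fix$mask, skeletonize(fix$mask))
  scale <- fix$scale
  d_end <- pmin(
    sqrt((sk$pixels[, "col"] - 0.5 - fix$ends[1, 1] / scale)^2 +
           (sk$pixels[, "row"] - 0.5 - fix$ends[1, 2] / scale)^2),
    sqrt((sk$pixels[, "col"] - 0.5 - fix$ends[2, 1] / scale)^2 +
           (sk$pixels[, "row"] - 0.5 - fix$ends[2, 2] / scale)^2))
  mean(sk$radius_px[d_end > 3 * r_px + 2])
}

# Y-shaped mask: one stem, two arms, in pixel coordinates.
y_mask <- function(image_size_px = 128, stem_px = 40, arm_px = 35,
                   width_px = 3, fov_mm = 3) {
  scale <- fov_mm * 1000 / image_size_px
  j <- c(64, 64)                         # junction, px
  stem0 <- j - c(0, stem_px)
  a1 <- j + arm_px * c(cos(35 * pi / 180), sin(35 * pi / 180))
  a2 <- j + arm_px * c(cos(145 * pi / 180), sin(145 * pi / 180))
  m <- matrix(FALSE, image_size_px, image_size_px)
  m <- octaphen:::paint_tube(m, rbind(stem0, j), width_px)
  m <- octaphen:::paint_tube(m, rbind(j, a1), width_px)
  m <- octaphen:::paint_tube(m, rbind(j, a2), width_px)
  vessel_mask(m, scale)
}

# Semicircular arc of radius R_um centered in the image.
semicircle_mask <- function(R_um = 900, tube_radius_um = 18,
                            image_size_px = 512, fov_mm = 3) {
  th <- seq(0, pi, length.out = 720)
  ctr <- c(fov_mm * 500, fov_mm * 500)
  pts <- cbind(ctr[1] + R_um * cos(th), ctr[2] + R_um * sin(th))
  rasterize_tube(pts, tube_radius_um, image_size_px, fov_mm)
}

# Exclusion disk of faz_radius_um bounded by a vessel ring, with radial
# capillary spokes fragmenting the surrounding background the way the
# perifoveal mesh does (otherwise the empty annulus around the ring,
# not the FAZ, would be the largest vessel-free central component).
faz_ring_mask <- function(faz_radius_um = 300, ring_radius_um = 10,
                          image_size_px = 512, fov_mm = 3,
                          n_spokes = 12) {
  ctr <- c(fov_mm * 500, fov_mm * 500)
  rc <- faz_radius_um + ring_radius_um + 2
  th <- seq(0, 2 * pi, length.out = 1024)
  pts <- cbind(ctr[1] + rc * cos(th), ctr[2] + rc * sin(th))
  scale <- fov_mm * 1000 / image_size_px
  m <- matrix(FALSE, image_size_px, image_size_px)
  m <- octaphen:::paint_tube(m, pts / scale, ring_radius_um / scale)
  for (a in seq(0, 2 * pi, length.out = n_spokes + 1)[-1]) {
    sp <- rbind(ctr + rc * c(cos(a), sin(a)),
                ctr + 900 * c(cos(a), sin(a)))
    m <- octaphen:::paint_tube(m, sp / scale, ring_radius_um / scale)
  }
  vessel_mask(m, scale)
}

# Brute-force two-sample KS oracle: evaluate both ECDFs at every pooled
# sample point by direct counting. Independent of stats::ecdf.
ks_brute <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Pure Murray tree (no FAZ ring/spokes) -> pruned graph, for topology and
# Murray-score tests.
murray_tree_graph <- function(seed, murray_exponent = 3, symmetry = 0.8,
                              image_size_px = 512) {
  tr <- generate_tree(tree_spec(seed = seed, murray_exponent = murray_exponent,
                                symmetry = symmetry,
                                faz_ring = FALSE, n_spokes = 0))
  m <- rasterize_tree(tr, image_size_px, 3)
  m <- clean_mask(m, min_component_px = 0, fill_holes_px = 30)
  list(tree = tr, mask = m, graph = mask_to_graph(m, 10))
}

# Small cohort for statistics tests.
test_cohort <- function(n = 60, seed = 1, effects = list(),
                        change = c(), rho = 0.5, miss = 0.15) {
  generate_cohort(cohort_sim_params(
    n_participants = n, effect_sizes = effects, change_effects = change,
    within_participant_corr = rho, missing_followup_fraction = miss,
    seed = seed))$table
}
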