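# Phenotype panel: regions, densities, FAZ, tortuosity, Murray KS score,
# symmetry, bifurcation distance, full-record computation.

test_that("region masks match the ETDRS-style scale arithmetic", {
  rg <- make_region_masks(c(512, 512), 3000 / 512)
  # foveal circle: 1 mm diameter -> radius 85.33 px
  expect_equal(500 / (3000 / 512), 85 + 1 / 3, tolerance = 1e-9)
  expect_lt(abs(sum(rg$foveal_circle) - pi * 85.33^2) / (pi * 85.33^2), 0.01)
  expect_equal(sum(rg$foveal_circle & rg$parafoveal_ring), 0)
  # parafoveal outer diameter equals the fov: ring touches the edge
  expect_true(any(rg$parafoveal_ring[256, c(1, 512)]))
  expect_error(make_region_masks(c(128, 128), 3000 / 128,
                                 parafoveal_outer_diameter_mm = 4),
               "exceeds")
})

test_that("vessel density is the exact white-pixel fraction", {
  m <- vessel_mask(matrix(FALSE, 64, 64), 10)
  region <- matrix(FALSE, 64, 64); region[1:32, ] <- TRUE
  expect_equal(vessel_density(m, region), 0)
  m2 <- vessel_mask(matrix(TRUE, 64, 64), 10)
  expect_equal(vessel_density(m2, region), 1)
  m3 <- vessel_mask(matrix(FALSE, 64, 64), 10)
  m3[1:16, ] <- TRUE                         # exactly half the region
  expect_identical(vessel_density(m3, region), 0.5)
  expect_error(vessel_density(m, matrix(FALSE, 64, 64)), "empty region")
})

test_that("regional densities recombine to the global density", {
  m <- murray_tree_graph(4)$mask
  rg <- make_region_masks(dim(m), attr(m, "scale_um_per_px"))
  inner <- rg$foveal_circle | rg$parafoveal_ring
  outer <- !inner
  d_global <- vessel_density(m, matrix(TRUE, nrow(m), ncol(m)))
  d_in <- vessel_density(m, inner); d_out <- vessel_density(m, outer)
  w <- sum(inner) / length(m)
  expect_equal(w * d_in + (1 - w) * d_out, d_global, tolerance = 1e-12)
})

test_that("FAZ detection recovers a 300-um exclusion disk within 5%", {
  m <- faz_ring_mask(300, 10, 512, 3)
  rg <- make_region_masks(dim(m), attr(m, "scale_um_per_px"))
  faz <- detect_faz(m, rg$central_region)
  expect_lt(abs(faz$faz_area_mm2 - pi * 0.09) / (pi * 0.09), 0.05)
  expect_true(any(faz$faz_mask))
})

test_that("FAZ takes the largest vessel-free pocket under the max rule", {
  m <- matrix(TRUE, 256, 256)
  m[100:109, 100:109] <- FALSE               # 100 px pocket
  m[140:159, 120:139] <- FALSE               # 400 px pocket
  vm <- vessel_mask(m, 3000 / 256)
  rg <- make_region_masks(dim(vm), attr(vm, "scale_um_per_px"))
  faz <- detect_faz(vm, rg$central_region)
  expect_equal(faz$faz_area_px, 400)
  # fully vascularized central region errors
  expect_error(detect_faz(vessel_mask(matrix(TRUE, 64, 64), 10),
                          matrix(TRUE, 64, 64)), "vessel-free")
})

test_that("all-false mask yields FAZ equal to the whole search region", {
  vm <- vessel_mask(matrix(FALSE, 256, 256), 3000 / 256)
  rg <- make_region_masks(dim(vm), attr(vm, "scale_um_per_px"))
  faz <- detect_faz(vm, rg$central_region)
  expect_equal(faz$faz_area_px, sum(rg$central_region))
})

test_that("tortuosity: straight = 1, semicircle = pi/2 within 2%", {
  g_line <- mask_to_graph(straight_tube_mask(4, 25, 256)$mask, 10)
  expect_equal(as.numeric(mean_tortuosity(g_line)), 1, tolerance = 0.005)
  g_semi <- mask_to_graph(semicircle_mask(), 10)
  expect_equal(as.numeric(mean_tortuosity(g_semi)), pi / 2,
               tolerance = 0.02)
})

test_that("tortuosity is rotation-invariant within rasterization tolerance", {
  vals <- vapply(c(0, 30, 75), function(rot) {
    th <- seq(0, pi, length.out = 720) + rot * pi / 180
    ctr <- c(1500, 1500)
    pts <- cbind(ctr[1] + 900 * cos(th), ctr[2] + 900 * sin(th))
    g <- mask_to_graph(rasterize_tube(pts, 18, 512, 3), 10)
    as.numeric(mean_tortuosity(g))
  }, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
})

test_that("sinusoid tortuosity matches the quadrature oracle within 2%", {
  A_um <- 60; lambda <- 1200                  # one period across the chord
  x <- seq(0, lambda, length.out = 1200)
  pts <- cbind(900 + x, 1500 + A_um * sin(2 * pi * x / lambda))
  g <- mask_to_graph(rasterize_tube(pts, 15, 512, 3), 10)
  oracle <- integrate(function(t)
    sqrt(1 + (2 * pi * A_um / lambda)^2 * cos(2 * pi * t / lambda)^2),
    0, lambda)$value / lambda
  expect_equal(as.numeric(mean_tortuosity(g)), oracle, tolerance = 0.02)
})

test_that("loops are excluded from tortuosity and counted", {
  g_ring <- mask_to_graph(faz_ring_mask(300, 10, 512, 3, n_spokes = 0), 10)
  expect_error(mean_tortuosity(g_ring), "positive chord")
})

test_that("KS statistic equals the brute-force ECDF oracle exactly", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- round(rnorm(n1), sample(0:2, 1))    # rounding forces ties
    y <- round(rnorm(n2, sample(c(0, 0.5), 1)), sample(0:2, 1))
    expect_identical(octaphen:::ks_statistic(x, y), ks_brute(x, y))
  }
  # disjoint supports give the maximal score
  expect_equal(octaphen:::ks_statistic(1, 2), 1)
  # agreement with stats::ks.test on tie-free samples
  set.seed(7)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  expect_equal(octaphen:::ks_statistic(x, y),
               unname(suppressWarnings(ks.test(x, y)$statistic)))
})

test_that("Murray KS is zero for an exact-law tree (analytic radii)", {
  tr <- generate_tree(tree_spec(seed = 5, murray_exponent = 3))
  bt <- tr$ground_truth$bifurcations
  # one-ulp noise from the cube/cube-root round trip is not a deviation
  x <- signif(bt$parent_radius_um^3, 8)
  y <- signif(bt$d1_radius_um^3 + bt$d2_radius_um^3, 8)
  expect_identical(octaphen:::ks_statistic(x, y), 0)
})

test_that("KS score is missing below the bifurcation minimum, with a log", {
  g <- mask_to_graph(y_mask(), 10)           # single bifurcation
  ks <- murray_ks_score(g, min_bifurcations = 5)
  expect_true(is.na(ks))
  expect_equal(attr(ks, "n_bifurcations"), 1)
})

test_that("symmetry ratio: exact cases and generator recovery", {
  bt <- tibble::tibble(node = 1, parent_segment = 1,
                       parent_radius_um = 12,
                       d1_radius_um = 20, d2_radius_um = 10)
  expect_equal(mean_symmetry_ratio(bt), 0.5)
  bt2 <- tibble::tibble(node = 1:2, parent_segment = 1:2,
                        parent_radius_um = c(10, 8),
                        d1_radius_um = c(7, 6), d2_radius_um = c(7, 6))
  expect_equal(mean_symmetry_ratio(bt2), 1)
  res <- murray_tree_graph(8, symmetry = 0.7)
  expect_equal(mean_symmetry_ratio(res$graph), 0.7, tolerance = 0.05)
})

test_that("mean radius: uniform tube, empty network, tapering bounds", {
  fix <- straight_tube_mask(8, 15, 512)
  g <- mask_to_graph(fix$mask, 10)
  expect_equal(mean_radius(g), 8 * fix$scale, tolerance = 0.5 * fix$scale)
  empty <- split_by_caliber(g, 1e6)$large
  expect_true(is.na(mean_radius(empty)))
  res <- murray_tree_graph(3)
  r <- mean_radius(res$graph)
  gt_r <- res$tree$ground_truth$segments$radius_um
  expect_gt(r, min(gt_r) * 0.8)
  expect_lt(r, max(gt_r) * 1.2)
})

test_that("bifurcation distance matches the generator on a deep tree", {
  res <- murray_tree_graph(6)
  got <- mean_bifurcation_distance(res$graph)
  want <- res$tree$ground_truth$mean_internal_arc_um
  expect_equal(got, want, tolerance = 2 * 5.86 / want * 2)
})

test_that("compute_phenotypes is deterministic and complete on a tree", {
  tr <- generate_tree(tree_spec(seed = 10))
  m <- rasterize_tree(tr, 512, 3)
  rec1 <- compute_phenotypes(m)
  rec2 <- compute_phenotypes(m)
  attr(rec1, "faz_mask") <- NULL; attr(rec2, "faz_mask") <- NULL
  expect_identical(rec1, rec2)
  expect_true(rec1$parafoveal_vd > 0 && rec1$parafoveal_vd < 1)
  expect_equal(rec1$faz_area_mm2, pi * 0.09, tolerance = 0.05)
  expect_gte(rec1$tortuosity_small, 1)
  expect_gt(rec1$n_bifurcations, 5)
})

test_that("compute_phenotypes on an all-false mask gives zero densities and missing metrics", {
  vm <- vessel_mask(matrix(FALSE, 256, 256), 3000 / 256)
  rec <- compute_phenotypes(vm)
  expect_equal(rec$parafoveal_vd, 0)
  expect_equal(rec$foveal_vd, 0)
  expect_true(is.na(rec$ks_score))
  expect_true(is.na(rec$radius_large_um))
  expect_equal(rec$branching_points, 0L)
})
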