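# Synthetic vascular tree generator: radius law, tortuosity geometry,
# FAZ exclusion, rasterization accuracy, determinism.

test_that("every bifurcation satisfies the generalized radius law exactly", {
  for (k in c(3, 2.6, 2.2, 1.8)) {
    tr <- generate_tree(tree_spec(seed = 11, murray_exponent = k,
                                  symmetry = 0.75))
    bt <- tr$ground_truth$bifurcations
    expect_gt(nrow(bt), 0)
    dev <- abs(bt$parent_radius_um^k -
                 (bt$d1_radius_um^k + bt$d2_radius_um^k))
    expect_lt(max(dev / bt$parent_radius_um^k), 1e-12)
    expect_equal(bt$d2_radius_um / bt$d1_radius_um,
                 rep(0.75, nrow(bt)), tolerance = 1e-12)
  }
})

test_that("symmetric Murray split halves flow: r1 = r2 = rp / 2^(1/3)", {
  tr <- generate_tree(tree_spec(seed = 2, murray_exponent = 3, symmetry = 1))
  bt <- tr$ground_truth$bifurcations
  expect_equal(bt$d1_radius_um, bt$parent_radius_um / 2^(1 / 3),
               tolerance = 1e-12)
  expect_equal(bt$d1_radius_um, bt$d2_radius_um, tolerance = 1e-12)
})

test_that("zero tortuosity amplitude gives straight segments (arc == chord)", {
  tr <- generate_tree(tree_spec(seed = 4, tortuosity_amplitude = 0))
  gt <- tr$ground_truth$segments
  expect_equal(gt$arc_um, gt$chord_um, tolerance = 1e-9)
})

test_that("tortuosity ground truth: arc >= chord, equality iff amplitude 0", {
  tr <- generate_tree(tree_spec(seed = 4, tortuosity_amplitude = 0.08))
  gt <- tr$ground_truth$segments
  expect_true(all(gt$arc_um >= gt$chord_um))
  expect_true(all(gt$arc_um > gt$chord_um + 1e-6))
  # analytic check: arc of y = A L sin(2 pi t) over the chord via quadrature
  A <- 0.08
  f <- function(x) sqrt(1 + (2 * pi * A)^2 * cos(2 * pi * x)^2)
  expected_ratio <- integrate(f, 0, 1)$value
  expect_equal(gt$arc_um / gt$chord_um, rep(expected_ratio, nrow(gt)),
               tolerance = 1e-4)
})

test_that("no vessel pixel enters the FAZ disk after rasterization", {
  for (seed in c(1, 7)) {
    tr <- generate_tree(tree_spec(seed = seed))
    m <- rasterize_tree(tr, 512, 3)
    scale <- attr(m, "scale_um_per_px")
    ctr <- 512 / 2 + 0.5
    d_px <- sqrt(outer(((1:512) - ctr)^2, ((1:512) - ctr)^2, "+"))
    faz_px <- 300 / scale
    expect_equal(sum(m[d_px < faz_px]), 0)
  }
})

test_that("generation is deterministic for a fixed seed", {
  t1 <- generate_tree(tree_spec(seed = 99))
  t2 <- generate_tree(tree_spec(seed = 99))
  expect_identical(t1$ground_truth, t2$ground_truth)
  expect_identical(t1$segments[[5]]$points, t2$segments[[5]]$points)
  t3 <- generate_tree(tree_spec(seed = 100))
  expect_false(identical(t1$ground_truth$segments$arc_um,
                         t3$ground_truth$segments$arc_um))
})

test_that("infeasible geometry errors instead of cropping", {
  expect_error(generate_tree(tree_spec(seed = 1, initial_length_um = 2500,
                                       branch_levels = 3)),
               "infeasible")
})

test_that("rasterized stadium area matches the analytic value within 2%", {
  # horizontal tube: radius 5 px, centerline length 100 px
  n <- 256; fov <- 3; scale <- fov * 1000 / n
  pts <- rbind(c(78, 128), c(178, 128)) * scale
  m <- rasterize_tube(pts, 5 * scale, n, fov)
  analytic <- 2 * 5 * 100 + pi * 25
  expect_lt(abs(sum(m) - analytic) / analytic, 0.02)
})

test_that("FAZ scale arithmetic: 300 um at 512 px / 3 mm is 51.2 px", {
  tr <- generate_tree(tree_spec(seed = 1))
  m <- rasterize_tree(tr, 512, 3)
  expect_equal(attr(m, "scale_um_per_px"), 3000 / 512)
  expect_equal(300 / attr(m, "scale_um_per_px"), 51.2)
})

test_that("sub-resolution segments are flagged, not dropped", {
  tr <- generate_tree(tree_spec(seed = 1, root_radius_um = 6,
                                branch_levels = 3, faz_ring = FALSE,
                                n_spokes = 0))
  m <- rasterize_tree(tr, 128, 3)   # 23.4 um/px: everything sub-resolution
  gt <- attr(m, "ground_truth")
  expect_gt(length(gt$sub_resolution_segments), 0)
  expect_gt(sum(m), 0)
})

test_that("rasterized FAZ area converges to pi r^2 with resolution", {
  errs <- vapply(c(256, 512, 1024), function(n) {
    m <- faz_ring_mask(300, 10, n, 3)
    regions <- make_region_masks(dim(m), attr(m, "scale_um_per_px"))
    faz <- detect_faz(m, regions$central_region)
    abs(faz$faz_area_mm2 - pi * 0.09) / (pi * 0.09)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12 | errs[-1] < 0.02))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], 0.02)
})
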