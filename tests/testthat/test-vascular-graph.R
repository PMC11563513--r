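# Skeletonization, radii, graph construction, pruning, caliber split.

test_that("a straight tube skeletonizes to a centerline within 1 px of the axis", {
  fix <- straight_tube_mask(5, 0, image_size_px = 256)
  sk <- skeletonize(fix$mask)
  expect_gt(nrow(sk$pixels), 50)
  # axis is the horizontal line y = center
  y_axis <- fix$ends[1, 2] / fix$scale
  interior <- abs(sk$pixels[, "col"] - 128) < 40
  expect_lt(max(abs(sk$pixels[interior, "row"] - 0.5 - y_axis)), 1)
  # skeleton is a subset of the mask and 1 px wide
  expect_true(all(fix$mask[sk$pixels]))
  smat <- matrix(FALSE, 256, 256); smat[sk$pixels] <- TRUE
  blocks <- smat[-256, -256] & smat[-1, -256] & smat[-256, -1] & smat[-1, -1]
  expect_false(any(blocks))
})

test_that("empty and degenerate masks are handled", {
  empty <- vessel_mask(matrix(FALSE, 32, 32), 10)
  sk <- skeletonize(empty)
  expect_equal(nrow(sk$pixels), 0)
  g <- build_vessel_graph(radius_from_distance(empty, sk))
  expect_equal(nrow(g$segments), 0)
  # a filled disk collapses to a few central pixels
  disk <- matrix(FALSE, 64, 64)
  disk[as.matrix(expand.grid(20:44, 20:44))] <-
    outer((20:44 - 32)^2, (20:44 - 32)^2, "+") <= 144
  sk2 <- skeletonize(vessel_mask(disk, 10))
  expect_lte(nrow(sk2$pixels), 8)
})

test_that("Y mask yields 4 nodes, 3 segments, one degree-3 junction", {
  g <- mask_to_graph(y_mask(), prune_um = 10)
  expect_equal(nrow(g$segments), 3)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(sum(g$nodes$degree == 3), 1)
  expect_equal(sum(g$nodes$degree == 1), 3)
  expect_equal(branching_points(g), 1)
  # no junction-junction segment: bifurcation distance is missing
  expect_true(is.na(mean_bifurcation_distance(g)))
})

test_that("radius recovery: half-width 8 px band reads 46.9 um within 0.5 px", {
  fix <- straight_tube_mask(8, 0, image_size_px = 512,
                            offset_um = c(0, 2.3))
  est <- tube_mean_radius_px(fix, 8)
  expect_lt(abs(est - 8), 0.5)
  expect_lt(abs(est * fix$scale - 46.875), 0.5 * fix$scale)
})

test_that("radius recovery error is within 0.5 px across widths 4-20 px", {
  set.seed(5)
  for (r_px in c(2, 3, 5, 7, 10)) {
    for (ang in c(0, 27, 63)) {
      fix <- straight_tube_mask(r_px, ang, image_size_px = 512,
                                offset_um = runif(2, 0, 5.86))
      expect_lt(abs(tube_mean_radius_px(fix, r_px) - r_px), 0.5,
                label = paste("radius", r_px, "angle", ang))
    }
  }
})

test_that("radius in um is resolution-invariant within one pixel", {
  r256 <- tube_mean_radius_px(f1 <- straight_tube_mask(3, 33, 256), 3) *
    f1$scale
  f2 <- straight_tube_mask(6, 33, 512)     # same physical tube
  r512 <- tube_mean_radius_px(f2, 6) * f2$scale
  expect_lt(abs(r256 - r512), f1$scale)
})

test_that("skeleton pixels outside the mask are an invariant breach", {
  fix <- straight_tube_mask(4, 10, 128)
  sk <- skeletonize(fix$mask)
  sk$pixels[1, ] <- c(1L, 1L)              # corrupt: off-mask pixel
  expect_error(radius_from_distance(fix$mask, sk), "invariant")
})

test_that("collinear pixel path measures arc = chord = 100 steps exactly", {
  m <- matrix(FALSE, 128, 128)
  m[64, 10:110] <- TRUE                    # 101 collinear pixels
  g <- build_vessel_graph(radius_from_distance(
    vessel_mask(m, 5.86), skeletonize(vessel_mask(m, 5.86))))
  expect_equal(nrow(g$segments), 1)
  expect_equal(g$segments$arc_um, 100 * 5.86, tolerance = 1e-9)
  expect_equal(g$segments$chord_um, 100 * 5.86, tolerance = 1e-9)
})

test_that("a closed ring is kept as a loop with perimeter-accurate arc", {
  m <- faz_ring_mask(300, 10, 512, 3, n_spokes = 0)
  g <- mask_to_graph(m, prune_um = 10)
  expect_equal(nrow(g$segments), 1)
  expect_equal(g$segments$from, g$segments$to)
  ring_radius_px <- (300 + 12) / attr(m, "scale_um_per_px")
  perim_um <- 2 * pi * ring_radius_px * attr(m, "scale_um_per_px")
  expect_lt(abs(g$segments$arc_um - perim_um),
            2 * attr(m, "scale_um_per_px") + 0.01 * perim_um)
})

test_that("spur pruning removes short twigs, merges, and is idempotent", {
  # Y with one short daughter: pruning leaves one merged segment
  scale <- 3000 / 128
  m <- matrix(FALSE, 128, 128)
  m <- octaphen:::paint_tube(m, rbind(c(20, 64), c(100, 64)), 2.5)
  m <- octaphen:::paint_tube(m, rbind(c(60, 64), c(60, 57)), 2)
  g0 <- mask_to_graph(vessel_mask(m, scale), prune_um = 0)
  expect_equal(branching_points(g0), 1)
  g1 <- prune_spurs(g0, 150)
  expect_equal(branching_points(g1), 0)
  expect_equal(nrow(g1$segments), 1)
  # threshold 0 leaves the graph unchanged
  expect_identical(prune_spurs(g0, 0), g0)
  # idempotence at a fixed threshold
  g2 <- prune_spurs(g1, 150)
  expect_equal(g2$segments$arc_um, g1$segments$arc_um)
  expect_equal(nrow(g2$nodes), nrow(g1$nodes))
})

test_that("caliber split partitions segments and conserves arc length", {
  res <- murray_tree_graph(6)
  g <- res$graph
  halves <- split_by_caliber(g, 20)
  expect_equal(nrow(halves$large$segments) + nrow(halves$small$segments),
               nrow(g$segments))
  expect_identical(sum(halves$large$segments$arc_um) +
                     sum(halves$small$segments$arc_um),
                   sum(g$segments$arc_um))
  expect_true(all(halves$large$segments$mean_caliber_um > 20))
  expect_true(all(halves$small$segments$mean_caliber_um <= 20))
  # trivial cases
  all_large <- split_by_caliber(g, 0)
  expect_equal(nrow(all_large$small$segments), 0)
  expect_equal(nrow(all_large$large$segments), nrow(g$segments))
  all_small <- split_by_caliber(g, 1e6)
  expect_equal(nrow(all_small$large$segments), 0)
})

test_that("arc >= chord holds for every segment of every fixture", {
  fixtures <- list(mask_to_graph(y_mask(), 10),
                   murray_tree_graph(2)$graph,
                   mask_to_graph(semicircle_mask(), 10))
  for (g in fixtures) {
    expect_true(all(g$segments$arc_um >= g$segments$chord_um - 1e-9))
    expect_true(all(g$segments$arc_um > 0))
  }
})

test_that("branching-point count matches generator truth on pruned trees", {
  for (seed in c(3, 9, 17)) {
    res <- murray_tree_graph(seed)
    expect_equal(branching_points(res$graph),
                 res$tree$ground_truth$n_bifurcations,
                 label = paste("seed", seed))
  }
})
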