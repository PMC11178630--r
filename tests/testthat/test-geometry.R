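test_that("the template grid has 169 nodes spanning +/-30 mm about the gland centroid", {
  ph <- sphere_case()
  grid <- build_template_grid(ph)
  nodes <- grid_nodes(grid)
  expect_equal(nrow(nodes), 169)
  cen <- mask_centroid(ph$gland)
  expect_equal(range(nodes$x - cen[1]), c(-30, 30))
  expect_equal(range(nodes$y - cen[2]), c(-30, 30))
  # centre node sits exactly at the grid centre
  expect_equal(unname(grid_node_xy(grid, 7, 7)[1, ]), unname(cen[1:2]))
  # adjacent nodes are 5 mm apart along each in-plane axis
  expect_equal(unname(diff(grid_node_xy(grid, 1:2, c(1, 1))[, "x"])), 5)
  expect_equal(unname(diff(grid_node_xy(grid, c(1, 1), 1:2)[, "y"])), 5)
})

test_that("action quantization matches a brute-force round-and-clamp oracle", {
  ph <- sphere_case()
  grid <- build_template_grid(ph)
  oracle <- function(dx, dy, node) {
    # independent restatement: round half away from zero, then clamp
    r <- function(v) as.integer(trunc(v + sign(v) * 0.5))
    c(min(max(node[1] + r(dx), 1L), 13L), min(max(node[2] + r(dy), 1L), 13L))
  }
  deltas <- -10:10
  for (node in list(c(7L, 7L), c(1L, 13L), c(11L, 3L))) {
    for (dx in deltas) for (dy in deltas) {
      q <- quantize_action(c(dx, dy, 0), node, grid)
      expect_identical(q$node, oracle(dx, dy, node))
    }
  }
  # fractional rounding rule, half away from zero
  expect_identical(quantize_action(c(3.4, -3.5, 0), c(7L, 7L), grid)$node,
                   c(10L, 3L))
  # clamping at the grid edge
  expect_identical(quantize_action(c(9.9, 0, 0), c(11L, 7L), grid)$node,
                   c(13L, 7L))
  # identity move
  expect_identical(quantize_action(c(0, 0, 0), c(7L, 7L), grid)$node, c(7L, 7L))
})

test_that("quantization never leaves the grid and thresholds the firing channel", {
  ph <- sphere_case()
  grid <- build_template_grid(ph)
  set.seed(4)
  for (k in 1:200) {
    a <- c(runif(2, -10, 10), runif(1, -1, 1))
    node <- c(sample(1:13, 1), sample(1:13, 1))
    q <- quantize_action(a, node, grid)
    expect_true(all(q$node >= 1 & q$node <= 13))
    if (a[3] < -1 / 3) expect_false(q$fired)
    else expect_identical(q$depth_label, if (a[3] < 1 / 3) "apex" else "base")
  }
  expect_error(quantize_action(c(NA, 0, 0), c(7L, 7L), grid), "finite")
})

test_that("depth planes sit at quartiles of the gland extent and translate with it", {
  # gland spanning z in [10, 50] mm exactly: voxel centres 10..50
  vox <- array(0L, dim = c(5, 5, 64))
  vox[3, 3, 11:51] <- 1L
  g <- mask_volume(vox)
  dp <- depth_planes(g)
  expect_equal(unname(dp), c(20, 40))
  g2 <- mask_volume(vox, origin = c(0, 0, 7))  # translate by +7 mm
  expect_equal(unname(depth_planes(g2)), c(27, 47))
  # symmetric gland: planes symmetric about the centroid
  ph <- sphere_case()
  dp3 <- depth_planes(ph)
  cen_z <- mask_centroid(ph$gland)[3]
  expect_equal(dp3[["base"]] - cen_z, cen_z - dp3[["apex"]], tolerance = 0.1)
})

test_that("needle rasterization covers core_length/spacing voxels and clips at bounds", {
  ph <- sphere_case()
  tr <- rasterize_needle(c(7, 7), "apex", ph)
  expect_equal(mask_count(tr), 20)
  idx <- which(tr$voxels == 1L, arr.ind = TRUE)
  # one-voxel-thick column: constant (x, y)
  expect_equal(length(unique(idx[, 1])), 1)
  expect_equal(length(unique(idx[, 2])), 1)
  # core centred 5 mm inside the image top is clipped to 15 voxels
  vox <- array(0L, dim = c(32, 32, 24))
  vox[8:24, 8:24, 2:23] <- 1L
  g <- mask_volume(vox)
  case <- patient_case("C", g, g)
  grid <- build_template_grid(case)
  planes <- list(apex = 18.5, base = 18.5)  # 5 mm below the top centre 23
  col <- biopsyplan:::needle_column(c(7, 7), "apex", 20, grid, g, planes)
  expect_equal(col$k1 - col$k0 + 1L, 15L)
})

test_that("intersection lengths match analytic sphere chords within one voxel", {
  # odd shape puts the lesion centre on an exact voxel centre, so the
  # probe columns sit at exact integer offsets from it
  ph <- sphere_case(lesion_radius = 5, gland_radii = c(24, 20, 20),
                    shape = c(65, 65, 49))
  d <- dim(ph$lesion$voxels)
  cen <- mask_centroid(ph$lesion)
  column_at <- function(x_off) {
    vox <- array(0L, dim = d)
    ix <- round(cen[1] + x_off) + 1L
    iy <- round(cen[2]) + 1L
    vox[ix, iy, ] <- 1L
    mask_volume(vox, ph$lesion$spacing, ph$lesion$origin)
  }
  # through the centre: chord = 10 mm
  expect_lt(abs(intersection_length(column_at(0), ph$lesion) - 10), 1 + 1e-9)
  # offset 3 mm: chord = 2*sqrt(25 - 9) = 8 mm
  expect_lt(abs(intersection_length(column_at(3), ph$lesion) - 8), 1 + 1e-9)
  # offset 4 mm: chord = 6 mm
  expect_lt(abs(intersection_length(column_at(4), ph$lesion) - 6), 1 + 1e-9)
  # disjoint masks intersect in 0
  empty <- mask_volume(array(0L, dim = d), ph$lesion$spacing, ph$lesion$origin)
  expect_equal(intersection_length(empty, ph$lesion), 0)
  expect_error(intersection_length(
    mask_volume(array(0L, dim = c(2, 2, 2))), ph$lesion), "shape")
})

test_that("CCL never exceeds core length or lesion chord plus one voxel", {
  ph <- sphere_case(lesion_radius = 7)
  grid <- build_template_grid(ph)
  chord <- max_axis_chord_mm(ph$lesion)
  for (node in list(c(7, 7), c(8, 7), c(6, 6), c(9, 9))) {
    for (depth in c("apex", "base")) {
      tr <- rasterize_needle(node, depth, ph, grid)
      ccl <- intersection_length(tr, ph$lesion)
      expect_lte(ccl, min(20, chord) + ph$lesion$spacing[3])
    }
  }
})

test_that("projected area and maximal chord match analytic sphere values", {
  ph <- sphere_case(lesion_radius = 8)
  expect_lt(abs(projected_area_mm2(ph$lesion) - pi * 64) / (pi * 64), 0.1)
  expect_lt(abs(max_axis_chord_mm(ph$lesion) - 16), 1.5)
})
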