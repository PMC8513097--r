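# Per-cell 3D metrics: volume, surface, ramification, polarity, intensity.

test_that("cell volume is calibrated voxel counting and additive", {
  cal <- analysis_calibration()
  m <- array(FALSE, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- TRUE               # 1000 voxels
  expect_equal(cell_volume(m, cal), 1000 * 0.3608^2 * 0.5)
  m2 <- m; m2[15:19, 15:19, 1:4] <- TRUE    # disjoint 100-voxel block
  expect_equal(cell_volume(m2, cal), cell_volume(m, cal) + 100 * 0.3608^2 * 0.5)
  expect_error(cell_volume(array(FALSE, c(3, 3, 3)), cal),
               class = "mgmorph_empty_mask")
})

test_that("digitized spheres reproduce analytic volume and surface", {
  cal <- calibration(1, 1)
  b <- ball_mask(20)
  expect_lt(abs(cell_volume(b, cal) - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.05)
  a <- cell_surface_area(b, cal)
  expect_lt(abs(a - 4 * pi * 400) / (4 * pi * 400), 0.03)
})

test_that("digitized cuboid surface is within 5% of the analytic area", {
  cal <- calibration(1, 1)
  m <- cuboid_mask(c(24, 18, 12))
  analytic <- 2 * (24 * 18 + 18 * 12 + 24 * 12)
  expect_lt(abs(cell_surface_area(m, cal) - analytic) / analytic, 0.05)
  # face counting mode: exact for an axis-aligned cuboid
  expect_equal(cell_surface_area(m, cal, method = "voxel_faces"), analytic)
})

test_that("ramification index has its closed forms and scale invariance", {
  r <- 7.3
  expect_equal(ramification_index(4 / 3 * pi * r^3, 4 * pi * r^2), 1.0)
  ri_cube <- ramification_index(1, 6)       # unit cube
  expect_equal(ri_cube, 6 / (4 * pi * (3 / (4 * pi))^(2 / 3)))
  expect_equal(round(ri_cube, 4), 1.2407)
  expect_equal(ramification_index(8 * 2, 4 * 5), ramification_index(2, 5))
  expect_error(ramification_index(0, 10), class = "mgmorph_bad_volume")
})

test_that("mean cell intensity equals a brute-force voxel loop", {
  set.seed(7)
  v <- array(rpois(6 * 5 * 4, 50), c(6, 5, 4))
  m <- array(runif(6 * 5 * 4) < 0.4, c(6, 5, 4))
  m[1, 1, 1] <- TRUE
  acc <- 0; n <- 0
  for (i in 1:6) for (j in 1:5) for (k in 1:4)
    if (m[i, j, k]) { acc <- acc + v[i, j, k]; n <- n + 1 }
  expect_equal(mean_cell_intensity(v, m), acc / n)
  expect_equal(mean_cell_intensity(array(42, dim(m)), m), 42)
  # mask covering exactly the bright half of a two-level stack
  v2 <- array(c(200, 10), c(2, 1, 1)); m2 <- array(c(TRUE, FALSE), c(2, 1, 1))
  expect_equal(mean_cell_intensity(v2, m2), 200)
})

test_that("polarity is ~0 for symmetric shapes and positive for asymmetric ones", {
  cal <- calibration(1, 1)
  expect_lt(polarity_index(ball_mask(15), cal), 0.01)
  cal2 <- calibration()
  sym <- rasterize_cell(cross_spec(arm = 11), cal2, c(224L, 224L, 48L))
  asym <- rasterize_cell(cross_spec(arm = 11, stretch = 1.5), cal2, c(224L, 224L, 48L))
  p_sym <- polarity_index(sym, cal2)
  p_asym <- polarity_index(asym, cal2)
  expect_lt(p_sym, 0.01)
  expect_gt(p_asym, p_sym + 0.01)
})

test_that("polarity is stable under axis rotations and reflections of the mask", {
  cal <- calibration(0.4, 0.4)            # isotropic so 90-degree turns are exact
  g <- generate_cell(cell_params(), seed = 77, center_um = c(20, 20, 12))
  spec <- g$spec
  spec$soma_center_um <- c(20, 20, 20)
  spec$segments[, c("z0", "z1")] <- spec$segments[, c("z0", "z1")] + 8
  m <- rasterize_cell(spec, cal, c(120L, 120L, 100L))
  p0 <- polarity_index(m, cal)
  rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]   # 90-degree rotation about z
  refl <- m[dim(m)[1]:1, , ]                      # reflection
  expect_lt(abs(polarity_index(rot, cal) - p0) / p0, 0.01)
  expect_lt(abs(polarity_index(refl, cal) - p0) / p0, 0.01)
})

test_that("degenerate coplanar masks are rejected by the polarity index", {
  m <- array(FALSE, c(10, 10, 5))
  m[2:8, 2:8, 3] <- TRUE                   # single plane: hull is flat
  expect_error(polarity_index(m, calibration()), class = "mgmorph_degenerate_hull")
})

test_that("mask Gauss filtering keeps solids, removes speckle, respects a 1-voxel band", {
  all_true <- array(TRUE, c(8, 8, 4))
  expect_true(all(gauss_filter_mask(all_true)))
  lone <- array(FALSE, c(9, 9, 3)); lone[5, 5, 2] <- TRUE
  expect_false(any(gauss_filter_mask(lone)))
  fix <- default_cell(31)
  sm <- gauss_filter_mask(fix$mask)
  expect_true(all(sm | !erode_mask(fix$mask)))
  expect_true(all(!sm | dilate_mask(fix$mask)))
})

test_that("skeletonization fixes 1-voxel curves and keeps components", {
  line <- array(FALSE, c(20, 5, 5)); line[3:17, 3, 3] <- TRUE
  expect_identical(skeletonize_3d(line), line)
  # two disjoint tubes -> two skeleton components
  two <- array(FALSE, c(40, 30, 14))
  two[4:36, 6:9, 6:9] <- TRUE
  two[4:36, 20:23, 6:9] <- TRUE
  sk <- skeletonize_3d(two)
  lab <- analyze_skeleton(sk, calibration(1, 1))
  expect_equal(lab$n_components, 2)
  expect_equal(lab$branch_count, 2)
})

test_that("a solid straight tube skeletonizes to a single path of the right length", {
  cal <- calibration()
  segs <- data.frame(parent = 0, x0 = 5, y0 = 8, z0 = 8, x1 = 30, y1 = 8, z1 = 8,
                     radius_um = 0.9)
  spec <- cell_spec(c(5, 8, 8), c(1.1, 1.1, 1.1), segs)
  m <- rasterize_cell(spec, cal, c(220L, 100L, 32L))
  an <- analyze_skeleton(skeletonize_3d(m, cal), cal)
  expect_equal(an$branch_count, 1)
  expect_lt(abs(an$tree_length - 25) / 25, 0.10)
})

test_that("skeleton branch decomposition matches hand-counted oracles", {
  cal <- calibration(0.5, 0.5)
  line <- array(FALSE, c(15, 5, 5)); line[3:13, 3, 3] <- TRUE  # 11 voxels
  an <- analyze_skeleton(line, cal)
  expect_equal(an$branch_count, 1)
  expect_equal(an$tree_length, 5.0)
  expect_equal(an$average_branch_length, 5.0)
  # symmetric Y of three 10-voxel arms
  y <- array(FALSE, c(30, 30, 5))
  y[15, 15, 3] <- TRUE
  y[15, 16:25, 3] <- TRUE                     # up
  for (s in 1:10) { y[15 - s, 15 - s, 3] <- TRUE; y[15 + s, 15 - s, 3] <- TRUE }
  an_y <- analyze_skeleton(y, cal, prune_um = 0)
  expect_equal(an_y$branch_count, 3)
  expect_equal(an_y$tree_length, sum(an_y$branch_lengths))
  expect_warning(an0 <- analyze_skeleton(array(FALSE, c(4, 4, 4)), cal))
  expect_equal(an0$branch_count, 0)
  expect_equal(an0$tree_length, 0)
})

test_that("branch counts on synthetic trees equal the generated truth", {
  cal <- calibration()
  for (s in c(61, 62, 63)) {
    g <- generate_cell(cell_params(), seed = s, center_um = c(20, 20, 12))
    m <- rasterize_cell(g$spec, cal, c(224L, 224L, 48L))
    an <- analyze_skeleton(skeletonize_3d(gauss_filter_mask(m), cal), cal)
    expect_equal(an$branch_count, g$truth$branch_count)
    expect_equal(an$tree_length, an$branch_count * an$average_branch_length)
  }
})

test_that("the morphometry record is consistent and round-trips through CSV", {
  cal <- calibration()
  fix <- default_cell(31)
  stk <- render_stack(list(iba1 = fix$mask), noise_model(seed = 2), cal)
  cm <- segment_cell(stk)
  rec <- compute_morphometry(stk$voxels, cm, cell_id = "c1")
  expect_gt(rec$ramification_index, 1)     # ramified cell is rougher than a sphere
  expect_gte(rec$polarity_index, 0)
  expect_equal(rec$tree_length_um, rec$branch_count * rec$average_branch_length_um)
  # sphere comparison: lower ramification
  ball <- ball_mask(16)
  cal1 <- calibration(1, 1)
  ri_sphere <- ramification_index(cell_volume(ball, cal1),
                                  cell_surface_area(ball, cal1))
  expect_gt(rec$ramification_index, ri_sphere)
  path <- tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  for (nm in names(rec)[vapply(rec, is.numeric, logical(1))])
    expect_equal(back[[nm]], rec[[nm]], tolerance = 0)
})
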