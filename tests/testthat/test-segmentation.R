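# Single-cell segmentation chain: 8-bit conversion, projection, scaling,
# Huang threshold, 3D threshold application, particle filtering.

test_that("8-bit conversion is linear, endpoint-exact and monotone", {
  a8 <- array(c(0, 17, 255), c(3, 1, 1))
  expect_equal(as.vector(to_8bit(a8)), c(0, 17, 255))  # already 8-bit: identity

  a16 <- array(c(0, 65535, 32768), c(3, 1, 1))
  out <- to_8bit(a16)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[2, 1, 1], 255)

  ramp <- array(seq(0, 4095, length.out = 64), c(64, 1, 1))
  expect_true(all(diff(as.vector(to_8bit(ramp))) >= 0))

  expect_true(all(to_8bit(array(7, c(4, 4, 2))) == 0))  # constant maps to 0
})

test_that("maximum projection honours plane sub-ranges", {
  a <- array(0, c(4, 4, 3))
  a[1, 1, 1] <- 5; a[3, 3, 2] <- 9
  expect_equal(max_project(a[, , 1, drop = FALSE]), a[, , 1])   # single plane
  p <- max_project(a)
  expect_equal(p[1, 1], 5); expect_equal(p[3, 3], 9)            # union of spots
  p12 <- max_project(a, planes = 1:2)
  expect_equal(p12, pmax(a[, , 1], a[, , 2]))
  # a 7-plane window, as used for neuronal lipofuscin
  b <- array(rep(1:10, each = 4), c(2, 2, 10))
  expect_equal(max_project(b, planes = 2:8), matrix(8, 2, 2))
  expect_error(max_project(a, planes = integer(0)), class = "mgmorph_empty_planes")
  expect_error(max_project(a, planes = 4), class = "mgmorph_empty_planes")
})

test_that("0.5-fold scaling halves dimensions and preserves means", {
  expect_equal(downscale_half(matrix(3, 8, 8)), matrix(3, 4, 4))
  expect_equal(dim(downscale_half(matrix(0, 1024, 1024))), c(512, 512))
  expect_equal(dim(downscale_half(matrix(0, 9, 7))), c(5, 4))
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2) * 100
  expect_equal(mean(downscale_half(cb)), mean(cb))
})

test_that("Huang threshold equals exhaustive minimization of the fuzziness objective", {
  set.seed(402)
  for (i in 1:120) {
    counts <- random_histogram()
    expect_identical(huang_threshold(counts), huang_bruteforce(counts))
  }
})

test_that("Huang threshold separates a two-delta histogram and is count-scale invariant", {
  counts <- integer(256); counts[10 + 1] <- 500; counts[200 + 1] <- 500
  t <- huang_threshold(counts)
  expect_gte(t, 10); expect_lt(t, 200)
  # the induced binary split puts the two levels on opposite sides
  expect_true(10 <= t && 200 > t)
  expect_identical(huang_threshold(counts * 2L), t)
  one <- integer(256); one[42] <- 10
  expect_error(huang_threshold(one), class = "mgmorph_degenerate_histogram")
})

test_that("3D threshold application is strict and maps back from the 8-bit domain", {
  v <- array(c(10, 20, 200, 250), c(2, 2, 1))
  expect_true(all(apply_threshold_3d(v, 5)))
  expect_false(any(apply_threshold_3d(v, 250)))
  expect_false(any(apply_threshold_3d(v, 300)))
  # strict ">": voxels exactly at the threshold are background
  expect_equal(sum(apply_threshold_3d(v, 20)), 2)
  # 8-bit level t maps to min + t/255 * (max - min)
  m <- apply_threshold_3d(v, 127.5, source_range = c(10, 250))
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("monotone affine rescaling leaves the segmentation mask unchanged", {
  fix <- default_cell(31)
  stk <- render_stack(list(iba1 = fix$mask), noise_model(seed = 3), calibration())
  v <- stk$voxels
  m1 <- segment_cell(v)
  for (ab in list(c(3, 7), c(0.25, 100))) {
    m2 <- segment_cell(ab[1] * v + ab[2])
    expect_identical(m1$voxels, m2$voxels)
  }
})

test_that("particle filter enforces the 10,000-voxel minimum inclusively", {
  # 9,999-voxel and 10,000-voxel cuboids in one volume
  m <- array(FALSE, c(60, 60, 24))
  m[2:21, 2:26, 2:21] <- TRUE                    # 20*25*20 = 10,000
  m[30:49, 30:54, 2:21] <- TRUE
  m[49, 54, 21] <- FALSE                         # 10,000 - 1 = 9,999
  cm <- particle_filter(m, segmentation_params())
  expect_equal(cm$component_count, 1)
  expect_equal(cm$voxel_count, 10000)
  expect_true(cm$voxels[2, 2, 2])                # 10,000-voxel block retained
  expect_false(any(cm$voxels[30:49, 30:54, 2:21]))  # 9,999-voxel block removed
})

test_that("particle filter removes speckle, is idempotent, and errors on empty result", {
  fix <- default_cell(32)
  m <- fix$mask
  set.seed(9)
  speck <- array(FALSE, dim(m))
  speck[sample(which(!dilate_mask(m)), 200)] <- TRUE  # clear of the cell
  expect_warning(cm <- particle_filter(m | speck, segmentation_params()), NA)
  expect_equal(cm$component_count, 1)
  expect_equal(sum(cm$voxels), sum(m))           # exactly the cell survives
  cm2 <- particle_filter(cm$voxels, segmentation_params())
  expect_identical(cm2$voxels, cm$voxels)        # idempotent
  expect_error(particle_filter(speck, segmentation_params()),
               class = "mgmorph_no_cell")
})

test_that("seeded cropping is an identity at full size and idempotent", {
  a <- array(seq_len(4 * 5 * 3), c(4, 5, 3))
  full <- extract_single_cell(a, c(2, 3, 2), dim(a))
  expect_equal(as.vector(full), as.vector(a))
  c1 <- extract_single_cell(a, c(2, 3, 2), c(3, 3, 3))
  c2 <- extract_single_cell(c1, round(dim(c1) / 2 + 0.5), dim(c1))
  expect_equal(as.vector(c2), as.vector(c1))
  expect_error(extract_single_cell(a, c(9, 1, 1), c(2, 2, 2)),
               class = "mgmorph_bad_seed")
})

test_that("two-cell stacks crop into per-cell masks matching per-cell truths", {
  cal <- calibration()
  g1 <- generate_cell(cell_params(), seed = 41, center_um = c(20, 20, 12))
  g2 <- generate_cell(cell_params(), seed = 42, center_um = c(20, 20, 12))
  m1 <- rasterize_cell(g1$spec, cal, c(224L, 224L, 48L))
  m2 <- rasterize_cell(g2$spec, cal, c(224L, 224L, 48L))
  big <- array(FALSE, c(224L, 448L, 48L))
  big[, 1:224, ] <- m1
  big[, 225:448, ] <- m2
  stk <- render_stack(list(iba1 = big), noise_model(seed = 1), cal)
  vv <- cal$xy_um_per_px^2 * cal$z_um_per_voxel
  for (cell in list(list(seed_col = 112, truth = g1$truth),
                    list(seed_col = 336, truth = g2$truth))) {
    crop <- extract_single_cell(stk$voxels, c(112, cell$seed_col, 24),
                                c(224, 224, 48))
    cm <- segment_cell(crop, cal)
    vol <- cm$voxel_count * vv
    expect_lt(abs(vol - cell$truth$volume_um3) / cell$truth$volume_um3, 0.10)
  }
})

test_that("full chain recovers noiseless synthetic cells within a 1-voxel band", {
  cal <- calibration()
  for (s in c(51, 52, 53)) {
    g <- generate_cell(cell_params(), seed = s, center_um = c(20, 20, 12))
    truth_mask <- rasterize_cell(g$spec, cal, c(224L, 224L, 48L))
    stk <- render_stack(list(iba1 = truth_mask),
                        noise_model(psf_sigma_xy = 0, psf_sigma_z = 0,
                                    shot_noise = FALSE, seed = 1), cal)
    cm <- segment_cell(stk)
    expect_equal(cm$component_count, 1)
    expect_true(all(cm$voxels | !erode_mask(truth_mask)))   # truth eroded 1 inside mask
    expect_true(all(!cm$voxels | dilate_mask(truth_mask)))  # mask inside truth dilated 1
    expect_lt(abs(sum(cm$voxels) - sum(truth_mask)) / sum(truth_mask), 0.10)
  }
})
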