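# Synthetic-cell generator: determinism, ground-truth fidelity, rendering.

test_that("cell generation is a pure function of (params, seed)", {
  a <- generate_cell(cell_params(), seed = 7)
  b <- generate_cell(cell_params(), seed = 7)
  expect_identical(a$spec, b$spec)
  expect_identical(a$truth, b$truth)
  c <- generate_cell(cell_params(), seed = 8)
  expect_false(identical(a$spec$segments, c$spec$segments))
})

test_that("degenerate generator parameters are rejected with a message", {
  expect_error(cell_params(n_primary = c(0L, 0L)), class = "mgmorph_bad_params")
})

test_that("a single straight process yields the forced truth metrics", {
  segs <- data.frame(parent = 0, x0 = 10, y0 = 10, z0 = 8,
                     x1 = 30, y1 = 10, z1 = 8, radius_um = 0.9)
  spec <- cell_spec(c(10, 10, 8), c(2.5, 2.5, 2.2), segs)
  truth <- cell_ground_truth(spec, seed = 1)
  expect_equal(truth$branch_count, 1L)
  expect_equal(truth$tree_length_um, 20)
  expect_equal(truth$average_branch_length_um, 20)
  expect_equal(truth$soma_area_um2, pi * 2.5 * 2.5)
})

test_that("a symmetric cross has ~zero centre-of-mass offset", {
  truth <- cell_ground_truth(cross_spec(), seed = 5, n_samples = 20000)
  expect_lt(truth$com_offset_um, 0.15)
  asym <- cell_ground_truth(cross_spec(arm = 11, stretch = 1.5), seed = 5,
                            n_samples = 20000)
  expect_gt(asym$com_offset_um, truth$com_offset_um)
})

test_that("rasterization is deterministic, connected, and volume-faithful", {
  cal <- calibration(0.5, 0.5)
  sp <- sphere_spec(10, center = c(16, 16, 16))
  m1 <- rasterize_cell(sp, cal, c(64L, 64L, 64L))
  m2 <- rasterize_cell(sp, cal, c(64L, 64L, 64L))
  expect_identical(m1, m2)
  vol <- sum(m1) * 0.5^2 * 0.5
  expect_lt(abs(vol - 4188.8) / 4188.8, 0.10)
  # a cross rasterizes to exactly one 26-connected component
  cr <- rasterize_cell(cross_spec(), calibration(), c(224L, 224L, 48L))
  an <- analyze_skeleton(skeletonize_3d(cr), calibration())
  expect_equal(an$n_components, 1)
  # boundary-touching cells are rejected
  expect_error(rasterize_cell(sphere_spec(10, center = c(3, 16, 16)),
                              cal, c(64L, 64L, 64L)),
               class = "mgmorph_cell_clipped")
})

test_that("noise-free, blur-free rendering is the exact two-level image", {
  fix <- default_cell(31)
  nm <- noise_model(psf_sigma_xy = 0, psf_sigma_z = 0, shot_noise = FALSE,
                    background = 20, foreground = 120)
  stk <- render_stack(list(iba1 = fix$mask), nm, calibration())
  expect_equal(stk$voxels, 20 + 100 * array(as.numeric(fix$mask), dim(fix$mask)))
  expect_gt(mean(stk$voxels[fix$mask]), mean(stk$voxels[!fix$mask]))
})

test_that("rendering is bit-identical under a fixed seed", {
  fix <- default_cell(31)
  s1 <- render_stack(list(iba1 = fix$mask), noise_model(seed = 4), calibration())
  s2 <- render_stack(list(iba1 = fix$mask), noise_model(seed = 4), calibration())
  expect_identical(s1$voxels, s2$voxels)
  s3 <- render_stack(list(iba1 = fix$mask), noise_model(seed = 5), calibration())
  expect_false(identical(s1$voxels, s3$voxels))
})

test_that("blurred renders recover the mask at the midpoint threshold within 2 voxels", {
  fix <- default_cell(31)
  nm <- noise_model(psf_sigma_xy = 1, psf_sigma_z = 0.6, shot_noise = FALSE,
                    background = 20, foreground = 120)
  stk <- render_stack(list(iba1 = fix$mask), nm, calibration())
  rec <- stk$voxels > 70
  expect_true(all(rec | !erode_mask(fix$mask, 2)))
  expect_true(all(!rec | dilate_mask(fix$mask, 2)))
})

test_that("channel masks must share one shape", {
  expect_error(render_stack(list(a = array(TRUE, c(4, 4, 2)),
                                 b = array(TRUE, c(4, 4, 3))),
                            noise_model(), calibration()),
               class = "mgmorph_bad_stack")
})

test_that("planted puncta have exact counts and projection area fractions", {
  cal <- calibration()
  region <- array(FALSE, c(90, 90, 24))
  region[10:80, 10:80, 6:18] <- TRUE
  pl <- generate_puncta(region, 12, radius_um = c(0.5, 0.7), cal = cal, seed = 3)
  expect_equal(pl$count, 12L)
  # pixel-counting oracle on the binary projection
  proj <- apply(pl$mask, c(1, 2), any)
  rproj <- apply(region, c(1, 2), any)
  expect_equal(pl$area_fraction, 100 * sum(proj & rproj) / sum(rproj))
  # empty channel
  p0 <- generate_puncta(region, 0, cal = cal, seed = 1)
  expect_equal(p0$count, 0L)
  expect_equal(p0$area_fraction, 0)
  expect_false(any(p0$mask))
  # impossible placements fail loudly
  tiny <- array(FALSE, c(14, 14, 8)); tiny[6:9, 6:9, 4:5] <- TRUE
  expect_error(generate_puncta(tiny, 40, radius_um = c(0.5, 0.7), cal = cal,
                               seed = 1, max_tries = 200),
               class = "mgmorph_placement_failure")
})

test_that("puncta placement is reproducible and non-touching", {
  cal <- calibration()
  region <- array(FALSE, c(80, 80, 20)); region[8:72, 8:72, 5:16] <- TRUE
  a <- generate_puncta(region, 8, cal = cal, seed = 11)
  b <- generate_puncta(region, 8, cal = cal, seed = 11)
  expect_identical(a$mask, b$mask)
  # 26-connected labelling must find exactly the planted count
  d3 <- dim(a$mask)
  lab <- suppressWarnings(
    particle_filter(a$mask, segmentation_params(min_particle_voxels = 1L), cal))
  expect_equal(lab$component_count, 8)
})

test_that("cohort generation reproduces requested effect sizes in the truth", {
  design0 <- list(groups = list(list(name = "A", n_mice = 2),
                                list(name = "B", n_mice = 2)),
                  cells_per_mouse = 2)
  td <- file.path(tempdir(), "coh_null")
  unlink(td, recursive = TRUE)
  truth <- generate_cohort(design0, td, seed = 5)
  for (k in c("soma_area_um2", "tree_length_um")) {
    d <- abs(mean(truth[[k]][truth$group == "A"]) - mean(truth[[k]][truth$group == "B"]))
    pooled_sem <- sd(truth[[k]]) / sqrt(4)
    expect_lt(d, 3 * pooled_sem)          # null design: no systematic shift
  }
  designB <- list(groups = list(list(name = "A", n_mice = 2),
                                list(name = "B", n_mice = 2,
                                     effects = list(soma_size = 1.3))),
                  cells_per_mouse = 3)
  tdB <- file.path(tempdir(), "coh_eff")
  unlink(tdB, recursive = TRUE)
  truthB <- generate_cohort(designB, tdB, seed = 6)
  ratio <- mean(truthB$soma_area_um2[truthB$group == "B"]) /
    mean(truthB$soma_area_um2[truthB$group == "A"])
  expect_lt(abs(ratio - 1.3) / 1.3, 0.12)
})

test_that("cohort regeneration under one seed is hash-identical", {
  design <- list(groups = list(list(name = "A", n_mice = 2)), cells_per_mouse = 1)
  t1 <- file.path(tempdir(), "coh_h1"); t2 <- file.path(tempdir(), "coh_h2")
  unlink(c(t1, t2), recursive = TRUE)
  generate_cohort(design, t1, seed = 21)
  generate_cohort(design, t2, seed = 21)
  f1 <- sort(list.files(t1, recursive = TRUE))
  expect_identical(f1, sort(list.files(t2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(t1, f1))
  h2 <- tools::md5sum(file.path(t2, f1))
  expect_identical(unname(h1), unname(h2))
})
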