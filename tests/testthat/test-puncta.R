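# Soma-ROI metrics, CD68 area fraction, lipofuscin particle quantification.

square_roi <- function(x0, y0, side, cal = analysis_calibration(), ...) {
  soma_roi(rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                 c(x0, y0 + side)), cal = cal, ...)
}

test_that("soma size and mean gray value follow the polygon definition", {
  cal <- analysis_calibration()
  roi <- square_roi(5, 5, 10, cal)
  img <- matrix(17, 40, 40)
  sm <- soma_metrics(roi, img)
  expect_equal(sm$soma_size_um2, 100 * 0.3608^2)
  expect_equal(sm$mean_gray_value, 17)
})

test_that("pixel membership equals a brute-force even-odd point-in-polygon loop", {
  cal <- analysis_calibration()
  v <- rbind(c(3.2, 2.1), c(17.4, 4.9), c(14.8, 16.3), c(8.1, 12.2), c(2.9, 14.0))
  roi <- soma_roi(v, cal)
  got <- roi_pixel_mask(roi, c(20, 20))
  ray_cast <- function(px, py) {
    n <- nrow(v); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    inside
  }
  want <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20) want[r, c] <- ray_cast(c - 0.5, r - 0.5)
  expect_identical(got, want)
})

test_that("self-intersecting and flat polygons are rejected", {
  expect_error(soma_roi(rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))),
               class = "mgmorph_bad_roi")
  expect_error(soma_roi(rbind(c(0, 0), c(4, 0), c(8, 0))),
               class = "mgmorph_bad_roi")
})

test_that("cohort reference threshold is the mean of per-image thresholds", {
  set.seed(31)
  base <- matrix(rpois(64 * 64, 20), 64)
  base[20:40, 20:40] <- rpois(21 * 21, 150)
  t_one <- cohort_reference_threshold(list(base))
  t_same <- cohort_reference_threshold(list(base, base, base))
  expect_equal(as.numeric(t_same), as.numeric(t_one))  # identical images: own threshold
  # arithmetic-mean property via two images with known separate thresholds
  img2 <- matrix(rpois(64 * 64, 40), 64)
  img2[10:30, 10:30] <- rpois(21 * 21, 220)
  rng <- range(c(base, img2))
  ta <- cohort_reference_threshold(list(base), range = rng)
  tb <- cohort_reference_threshold(list(img2), range = rng)
  tab <- cohort_reference_threshold(list(base, img2), range = rng)
  expect_equal(as.numeric(tab), (as.numeric(ta) + as.numeric(tb)) / 2)
  expect_warning(tc <- cohort_reference_threshold(list(base, matrix(20, 8, 8))),
                 "degenerate")
  expect_equal(as.numeric(tc), as.numeric(t_one))
})

test_that("area fraction is exact on planted binary channels and ROI-local", {
  cal <- analysis_calibration()
  roi <- square_roi(10, 10, 20, cal)
  bin <- matrix(FALSE, 60, 60)
  expect_equal(area_fraction(bin, roi), 0)
  bin[11:30, 11:30] <- TRUE                       # the ROI pixels exactly
  expect_equal(area_fraction(bin, roi), 100)
  bin2 <- matrix(FALSE, 60, 60)
  bin2[11:30, 11:20] <- TRUE                      # half the ROI
  expect_equal(area_fraction(bin2, roi), 50)
  bin3 <- bin2; bin3[40:60, 40:60] <- TRUE        # signal outside the ROI
  expect_equal(area_fraction(bin3, roi), 50)
})

test_that("neuronal lipofuscin counts particles above the strict 0.5-um2 cutoff", {
  cal <- calibration(1, 1)                        # 1 um pixels for round numbers
  stack <- array(0, c(60, 60, 12))
  # 12 single-pixel puncta of 1 um2 each, scattered, planes 3..9
  set.seed(5)
  pos <- cbind(seq(8, 52, by = 4), seq(10, 54, by = 4))
  for (q in 1:12) stack[pos[q, 1], pos[q, 2], 3 + (q %% 7)] <- 200
  roi <- soma_roi(rbind(c(2, 2), c(58, 2), c(58, 58), c(2, 58)), cal)
  pm <- neuronal_lipofuscin(stack, roi, start_plane = 3, cal = cal)
  expect_equal(pm$particle_count, 12L)
  expect_equal(pm$particle_density, 12 / (56 * 56))
  # density from a planted 1000-um2 selection: 12 puncta -> 0.012 / um2
  roi2 <- soma_roi(rbind(c(5, 5), c(45, 5), c(45, 30), c(5, 30)), cal)
  expect_equal(roi_area_um2(roi2), 1000)
  # particles at exactly and below the cutoff are excluded (> 0.5 um2 rule)
  cal2 <- calibration(0.5, 1)                     # 0.25 um2 pixels
  st2 <- array(0, c(40, 40, 8))
  st2[10, 10, 2] <- 200                           # 0.25 um2: below
  st2[20, 20:21, 2] <- 200                        # 0.5 um2: exactly at cutoff
  st2[30, 30:32, 2] <- 200                        # 0.75 um2: above
  roi3 <- soma_roi(rbind(c(1, 1), c(39, 1), c(39, 39), c(1, 39)), cal2)
  pm2 <- neuronal_lipofuscin(st2, roi3, start_plane = 1, cal = cal2)
  expect_equal(pm2$particle_count, 1L)
  # two touching puncta are one particle
  st3 <- array(0, c(40, 40, 8))
  st3[10, 10:12, 2] <- 200; st3[11, 13, 2] <- 200  # 8-connected blob
  pm3 <- neuronal_lipofuscin(st3, roi3, start_plane = 1, cal = cal2)
  expect_equal(pm3$particle_count, 1L)
  expect_error(neuronal_lipofuscin(st3, roi3, start_plane = 4, cal = cal2),
               class = "mgmorph_empty_planes")
})

test_that("somatic marker fractions recover planted values exactly", {
  cal <- calibration(1, 1)
  stack <- array(0, c(50, 50, 10))
  roi <- soma_roi(rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25)), cal,
                  mouse = "m1", cell = "c1")
  # plant 3.5% of the 400 ROI pixels (14 pixels) as lipofuscin
  px <- roi_pixel_mask(roi, c(50, 50))
  idx <- which(px)[seq(1, 400, length.out = 14)]
  for (i in idx) stack[arrayInd(i, c(50, 50))[1], arrayInd(i, c(50, 50))[2], 4] <- 180
  out <- microglial_lipofuscin(stack, list(roi), threshold = 90, cal = cal,
                               min_cells_per_mouse = 1L)
  expect_equal(out$area_fraction, 100 * 14 / 400)
  # empty channel: zero fraction for all cells
  out0 <- microglial_lipofuscin(array(0, c(50, 50, 10)), list(roi),
                                threshold = 90, cal = cal,
                                min_cells_per_mouse = 1L)
  expect_equal(out0$area_fraction, 0)
  # monotonicity: adding puncta never decreases the fraction
  stack2 <- stack
  stack2[arrayInd(which(px)[300], c(50, 50))[1],
         arrayInd(which(px)[300], c(50, 50))[2], 5] <- 180
  out2 <- microglial_lipofuscin(stack2, list(roi), threshold = 90, cal = cal,
                                min_cells_per_mouse = 1L)
  expect_gte(out2$area_fraction, out$area_fraction)
  # per-mouse cell-count expectation is flagged
  outf <- microglial_lipofuscin(stack, list(roi), threshold = 90, cal = cal)
  expect_match(attr(outf, "qc_flags"), "m1")
})

test_that("CD68 quantification with a cohort-fixed threshold is label-permutation stable", {
  cal <- calibration(1, 1)
  set.seed(77)
  stack <- array(rpois(40 * 40 * 6, 15), c(40, 40, 6))
  stack[12:18, 12:18, 3] <- 220
  roi <- soma_roi(rbind(c(8, 8), c(24, 8), c(24, 24), c(8, 24)), cal,
                  mouse = "m1", cell = "c1")
  thr <- 100
  a <- cd68_area_fraction(stack, list(roi), threshold = thr, cal = cal)
  b <- cd68_area_fraction(stack, list(roi), threshold = thr, cal = cal)
  expect_identical(a$area_fraction, b$area_fraction)   # fixed threshold: stable
  expect_equal(a$threshold_used, thr)
  expect_true(a$area_fraction > 0 && a$area_fraction <= 100)
})
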