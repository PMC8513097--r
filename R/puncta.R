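# Soma-ROI metrics and punctate-marker quantification: soma size and Iba1
# mean gray value, CD68 area fraction under a cohort-fixed threshold, and
# lipofuscin particle counts / densities / area fractions.

#' Soma size and mean gray value
#'
#' Measures one soma ROI on a 2D projection: `soma_size` is the polygon
#' (shoelace) area times the squared pixel size; the mean gray value is the
#' mean intensity over pixels whose centres fall inside the polygon
#' (even-odd rule).
#'
#' @param roi [soma_roi()].
#' @param image 2D intensity matrix (e.g. an Iba1 maximum projection).
#' @return list with `soma_size_um2` and `mean_gray_value`.
#' @export
soma_metrics <- function(roi, image) {
  stopifnot(is.matrix(image))
  px <- roi_pixel_mask(roi, dim(image))
  if (sum(px) == 0)
    mg_stop("ROI covers no pixel centres", "mgmorph_empty_roi")
  list(soma_size_um2 = roi_area_um2(roi),
       mean_gray_value = mean(image[px]))
}

#' Cohort-fixed reference threshold
#'
#' Binarization threshold for marker channels that must be comparable across
#' groups: the mean of per-image auto-thresholds over the reference (control
#' group) projections, then held constant for every group. Per-image
#' thresholds use the same Huang fuzzy-entropy algorithm as the segmentation
#' stage, computed on a 256-bin histogram over a common intensity range.
#' Degenerate (constant) images are excluded with a warning.
#'
#' @param images list of 2D matrices (reference-group projections).
#' @param range common intensity range for the 8-bit conversion; defaults to
#'   the pooled range over `images`.
#' @return threshold in source intensity units, with attribute
#'   `per_image` (the individual thresholds).
#' @export
cohort_reference_threshold <- function(images, range = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  if (is.null(range)) range <- base::range(unlist(lapply(images, base::range)))
  ts <- numeric(0)
  for (im in images) {
    t_i <- tryCatch({
      im8 <- to_8bit(im, range = range)
      threshold_to_source(huang_threshold(hist256(im8)), range)
    }, mgmorph_degenerate_histogram = function(e) NA_real_)
    if (is.na(t_i)) warning("degenerate image excluded from reference threshold")
    else ts <- c(ts, t_i)
  }
  if (length(ts) == 0)
    mg_stop("all reference images degenerate", "mgmorph_degenerate_histogram")
  structure(mean(ts), per_image = ts)
}

#' Area fraction of a binary signal within an ROI
#'
#' `100 * (positive pixels inside the ROI) / (pixels inside the ROI)` — the
#' CD68 (and somatic lipofuscin) readout.
#'
#' @param binary logical 2D matrix (thresholded projection).
#' @param roi [soma_roi()].
#' @return percent in `[0, 100]`.
#' @export
area_fraction <- function(binary, roi) {
  stopifnot(is.logical(binary))
  px <- roi_pixel_mask(roi, dim(binary))
  n <- sum(px)
  if (n == 0) mg_stop("ROI covers no pixel centres", "mgmorph_empty_roi")
  100 * sum(binary[px]) / n
}

# count 8-connected particles with calibrated area strictly above the cutoff;
# returns count and total positive pixels
count_particles <- function(binary, cal, min_area_um2 = 0.5) {
  d <- dim(binary)
  m3 <- array(binary, c(d, 1L))
  lab <- cpp_label3d(m3, dim(m3), 26L)       # 26-conn on one plane == 8-conn
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) return(list(count = 0L, areas = numeric(0)))
  px_area <- cal$xy_um_per_px^2
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  areas <- sizes * px_area
  list(count = sum(areas > min_area_um2), areas = areas)
}

puncta_measurement <- function(area_fraction, particle_count, roi_area_um2,
                               threshold_used, mouse = NA, cell = NA) {
  data.frame(mouse = as.character(mouse), cell = as.character(cell),
             area_fraction = area_fraction,
             particle_count = as.integer(particle_count),
             particle_density = particle_count / roi_area_um2,
             roi_area_um2 = roi_area_um2,
             threshold_used = threshold_used,
             stringsAsFactors = FALSE)
}

#' Neuronal lipofuscin particle density
#'
#' Projects a 7-plane window (maximum intensity) starting at `start_plane`,
#' binarizes it (per-image Huang threshold unless a cohort-fixed `threshold`
#' is supplied), restricts to the analysis region and counts 8-connected
#' particles whose calibrated area is strictly greater than `min_area_um2`
#' (default 0.5). Density is particles per um^2 of the region.
#'
#' @param x 3D array or `mg_stack` (lipofuscin autofluorescence channel).
#' @param roi [soma_roi()] delimiting the analysis region.
#' @param start_plane first plane of the projection window (1-based).
#' @param cal [calibration()].
#' @param n_planes window depth (7 in the reproduced protocol).
#' @param threshold optional fixed threshold in source units.
#' @param min_area_um2 particle-size cutoff (area, strictly greater than).
#' @return one-row `data.frame` with `area_fraction` (percent),
#'   `particle_count`, `particle_density` (1/um^2), `roi_area_um2`,
#'   `threshold_used`.
#' @export
neuronal_lipofuscin <- function(x, roi, start_plane, cal = calibration(),
                                n_planes = 7L, threshold = NULL,
                                min_area_um2 = 0.5) {
  v <- as_voxels(x)
  if (inherits(x, "mg_stack")) cal <- x$cal
  nz <- dim(v)[3]
  if (start_plane < 1 || start_plane + n_planes - 1 > nz)
    mg_stop("projection window outside stack depth", "mgmorph_empty_planes")
  proj <- max_project(v, planes = start_plane:(start_plane + n_planes - 1))
  bin <- binarize_projection(proj, threshold)
  px <- roi_pixel_mask(roi, dim(proj))
  if (sum(px) == 0) mg_stop("region outside image", "mgmorph_empty_roi")
  inside <- bin & px
  pc <- count_particles(inside, cal, min_area_um2)
  puncta_measurement(area_fraction = 100 * sum(inside) / sum(px),
                     particle_count = pc$count,
                     roi_area_um2 = roi_area_um2(roi),
                     threshold_used = attr(bin, "threshold"),
                     mouse = roi$mouse, cell = roi$cell)
}

# binarize a projection at a fixed threshold or a per-image Huang threshold
binarize_projection <- function(proj, threshold = NULL) {
  if (is.null(threshold)) {
    rng <- base::range(proj)
    p8 <- to_8bit(proj, range = rng)
    threshold <- threshold_to_source(huang_threshold(hist256(p8)), rng)
  }
  out <- proj > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Somatic marker quantification over a set of soma ROIs
#'
#' Shared machinery for the CD68 area fraction and microglial somatic
#' lipofuscin: binarized full-stack maximum projection, then per-soma area
#' fraction, particle count and density. `microglial_lipofuscin` logs a
#' flag for mice contributing fewer than `min_cells_per_mouse` somas
#' (12 in the reproduced protocol).
#'
#' @param x 3D array or `mg_stack` (marker channel).
#' @param somas list of [soma_roi()].
#' @param threshold binarization threshold in source units; typically the
#'   [cohort_reference_threshold()] for CD68, or `NULL` for a per-image
#'   Huang threshold.
#' @param cal [calibration()].
#' @param min_area_um2 particle-size cutoff for the counts.
#' @param min_cells_per_mouse per-mouse cell-count expectation to flag.
#' @return `data.frame` with one row per soma (see [neuronal_lipofuscin()]
#'   for columns); for `microglial_lipofuscin` the attribute `qc_flags`
#'   lists mice below the cell-count expectation.
#' @export
cd68_area_fraction <- function(x, somas, threshold, cal = calibration(),
                               min_area_um2 = 0.5) {
  v <- as_voxels(x)
  if (inherits(x, "mg_stack")) cal <- x$cal
  proj <- max_project(v)
  bin <- binarize_projection(proj, threshold)
  do.call(rbind, lapply(somas, function(roi) {
    px <- roi_pixel_mask(roi, dim(proj))
    if (sum(px) == 0) mg_stop("ROI covers no pixel centres", "mgmorph_empty_roi")
    inside <- bin & px
    pc <- count_particles(inside, cal, min_area_um2)
    puncta_measurement(100 * sum(inside) / sum(px), pc$count,
                       roi_area_um2(roi), attr(bin, "threshold"),
                       mouse = roi$mouse, cell = roi$cell)
  }))
}

#' @rdname cd68_area_fraction
#' @export
microglial_lipofuscin <- function(x, somas, threshold = NULL,
                                  cal = calibration(), min_area_um2 = 0.5,
                                  min_cells_per_mouse = 12L) {
  stopifnot(length(somas) >= 1)
  out <- cd68_area_fraction(x, somas, threshold, cal, min_area_um2)
  per_mouse <- table(out$mouse[!is.na(out$mouse)])
  low <- names(per_mouse)[per_mouse < min_cells_per_mouse & names(per_mouse) != "NA"]
  if (length(low))
    attr(out, "qc_flags") <- sprintf("mouse %s has %d cells (< %d expected)",
                                     low, as.integer(per_mouse[low]),
                                     min_cells_per_mouse)
  out
}
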