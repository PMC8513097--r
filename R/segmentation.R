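#' Segmentation parameters
#'
#' Defaults follow the single-cell segmentation chain of the reproduced
#' toolbox: threshold estimated with the Huang fuzzy-entropy algorithm on an
#' 8-bit, 0.5-fold scaled maximum-intensity projection, applied to the
#' unmodified 3D image, followed by removal of 26-connected particles below
#' 10,000 voxels.
#'
#' @param scale_factor in-plane scaling applied to the projection before
#'   threshold estimation (0 < scale_factor <= 1; only 1 and 0.5 are
#'   implemented, 0.5 being the pipeline default).
#' @param threshold_algorithm name of the auto-threshold ("huang").
#' @param min_particle_voxels minimum retained component size, in voxels of
#'   the grid the filter runs on.
#' @param connectivity 3D neighbourhood for particle analysis (6, 18 or 26).
#' @return list of class `mg_seg_params`.
#' @export
segmentation_params <- function(scale_factor = 0.5,
                                threshold_algorithm = "huang",
                                min_particle_voxels = 10000L,
                                connectivity = 26L) {
  stopifnot(scale_factor > 0, scale_factor <= 1,
            min_particle_voxels >= 1,
            connectivity %in% c(6L, 18L, 26L),
            identical(threshold_algorithm, "huang"))
  structure(list(scale_factor = scale_factor,
                 threshold_algorithm = threshold_algorithm,
                 min_particle_voxels = as.integer(min_particle_voxels),
                 connectivity = as.integer(connectivity)),
            class = "mg_seg_params")
}

#' Linear 8-bit conversion
#'
#' Maps intensities linearly from `[min, max]` of the input (or an explicit
#' source range) onto `[0, 255]` and rounds half up, as a display-range-free,
#' reproducible 8-bit conversion. A constant image maps to 0.
#'
#' @param x numeric array or matrix of intensities.
#' @param range optional length-2 source range; defaults to `range(x)`.
#' @return array of the same shape with integer values in `[0, 255]`; the
#'   source range used is attached as attribute `source_range`.
#' @export
to_8bit <- function(x, range = NULL) {
  v <- as_voxels(x)
  if (is.null(range)) range <- base::range(v)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    out <- array(0, dim(v))
  } else {
    out <- floor((v - lo) / (hi - lo) * 255 + 0.5)
    out[out < 0] <- 0
    out[out > 255] <- 255
  }
  attr(out, "source_range") <- c(lo, hi)
  out
}

#' Maximum-intensity projection
#'
#' Projects a 3D stack along z by the per-pixel maximum, optionally over a
#' contiguous sub-range of planes (e.g. the 7-plane window used for neuronal
#' lipofuscin).
#'
#' @param x 3D array (or `mg_stack`).
#' @param planes optional integer vector of z indices to project over.
#' @return 2D matrix.
#' @export
max_project <- function(x, planes = NULL) {
  v <- as_voxels(x)
  stopifnot(length(dim(v)) == 3)
  nz <- dim(v)[3]
  if (is.null(planes)) planes <- seq_len(nz)
  if (length(planes) == 0)
    mg_stop("empty plane range", "mgmorph_empty_planes")
  if (any(planes < 1 | planes > nz))
    mg_stop("plane range outside stack depth", "mgmorph_empty_planes")
  apply(v[, , planes, drop = FALSE], c(1, 2), max)
}

#' Halve a 2D image
#'
#' 0.5-fold scaling by 2x2 block averaging (bilinear interpolation at
#' half-pixel centres). Output dimensions are `ceiling(dim/2)`; odd edges
#' replicate the last row/column. A constant image stays constant and the
#' image mean is preserved up to edge effects.
#'
#' @param img 2D numeric matrix with both dimensions >= 2.
#' @return matrix of dimension `ceiling(dim(img)/2)`.
#' @export
downscale_half <- function(img) {
  stopifnot(is.matrix(img), nrow(img) >= 2, ncol(img) >= 2)
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% 2 == 1) img <- rbind(img, img[nr, , drop = FALSE])
  if (nc %% 2 == 1) img <- cbind(img, img[, ncol(img), drop = FALSE])
  nr2 <- nrow(img) / 2; nc2 <- ncol(img) / 2
  (img[seq(1, nrow(img), 2), seq(1, ncol(img), 2)] +
   img[seq(2, nrow(img), 2), seq(1, ncol(img), 2)] +
   img[seq(1, nrow(img), 2), seq(2, ncol(img), 2)] +
   img[seq(2, nrow(img), 2), seq(2, ncol(img), 2)]) / 4
}

# Huang-Wang fuzziness of a 256-bin histogram at candidate threshold t
# (0-based gray level; foreground is "> t"). Membership of gray g is
# 1 / (1 + |g - mu_class| / C) with C = gmax - gmin; the measure is the
# count-weighted Shannon entropy of the memberships.
huang_fuzziness <- function(counts, t) {
  g <- 0:255
  occ <- which(counts > 0) - 1L
  C <- max(occ) - min(occ)
  lo <- g <= t
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(Inf)
  mu0 <- sum(counts[lo] * g[lo]) / n0
  mu1 <- sum(counts[!lo] * g[!lo]) / n1
  u <- ifelse(lo, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
  s <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  sum(counts * s)
}

#' Huang fuzzy-entropy threshold
#'
#' Selects the 8-bit threshold minimizing the Huang-Wang measure of
#' fuzziness (Shannon entropy of class-mean-based memberships) over all
#' candidate levels between the lowest and highest occupied bins. Ties are
#' broken toward the lower level. Foreground is defined by the strict
#' comparison `intensity > threshold`.
#'
#' @param counts integer vector of 256 histogram counts for gray levels
#'   0..255.
#' @return integer threshold in `[gmin, gmax - 1]` where `gmin`/`gmax` are
#'   the lowest/highest occupied levels.
#' @export
huang_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  occ <- which(counts > 0) - 1L
  if (length(occ) < 2)
    mg_stop("degenerate histogram: fewer than two occupied gray levels",
            "mgmorph_degenerate_histogram")
  gmin <- min(occ); gmax <- max(occ)
  g <- 0:255
  C <- gmax - gmin
  csum <- cumsum(counts)
  cmom <- cumsum(counts * g)
  n <- csum[256]; m <- cmom[256]
  best_t <- NA_integer_; best_f <- Inf
  for (t in gmin:(gmax - 1L)) {
    n0 <- csum[t + 1L]; n1 <- n - n0
    mu0 <- cmom[t + 1L] / n0
    mu1 <- (m - cmom[t + 1L]) / n1
    u <- numeric(256)
    lo <- g <= t
    u[lo] <- 1 / (1 + abs(g[lo] - mu0) / C)
    u[!lo] <- 1 / (1 + abs(g[!lo] - mu1) / C)
    s <- -u * log(u) - (1 - u) * log1p(-u)
    s[u >= 1] <- 0
    f <- sum(counts * s)
    if (f < best_f - 1e-12) { best_f <- f; best_t <- t }
  }
  as.integer(best_t)
}

#' Histogram of an 8-bit image
#'
#' @param img8 array of integer values in `[0, 255]`.
#' @return integer vector of 256 counts.
#' @export
hist256 <- function(img8) {
  tabulate(as.integer(img8) + 1L, nbins = 256L)
}

# Map an 8-bit threshold back to source intensity units by inverting the
# linear 8-bit conversion.
threshold_to_source <- function(t8, source_range) {
  lo <- source_range[1]; hi <- source_range[2]
  lo + t8 / 255 * (hi - lo)
}

#' Apply an intensity threshold to a 3D stack
#'
#' A voxel is foreground iff `intensity > t` (strict). When `t` was estimated
#' on an 8-bit conversion, pass the conversion's `source_range` so the level
#' is mapped back to the unmodified image's units first.
#'
#' @param x 3D array (or `mg_stack`).
#' @param t threshold. Interpreted in source units unless `source_range` is
#'   given, in which case `t` is an 8-bit level.
#' @param source_range optional length-2 range used by the 8-bit conversion.
#' @return logical 3D array.
#' @export
apply_threshold_3d <- function(x, t, source_range = NULL) {
  v <- as_voxels(x)
  if (!is.null(source_range)) t <- threshold_to_source(t, source_range)
  out <- v > t
  attr(out, "threshold") <- t
  out
}

#' Remove small particles from a binary stack
#'
#' Labels 26-connected (configurable) components and discards those below
#' `min_particle_voxels`. Single-cell images are expected to
#' yield exactly one surviving cell; a different count raises a warning.
#'
#' @param mask logical 3D array.
#' @param params [segmentation_params()].
#' @param cal [calibration()] carried into the resulting mask.
#' @return object of class `mg_cell_mask`: list with `voxels` (logical 3D
#'   array), `cal`, `component_count`, `source_threshold` (if present on
#'   `mask`) and `voxel_count`.
#' @export
particle_filter <- function(mask, params = segmentation_params(),
                            cal = calibration()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  lab <- cpp_label3d(mask, dim(mask), params$connectivity)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0)
    mg_stop("no cell survives filter: mask is empty", "mgmorph_no_cell")
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- which(sizes >= params$min_particle_voxels)
  if (length(keep) == 0)
    mg_stop("no cell survives filter: all components below minimum particle volume",
            "mgmorph_no_cell")
  out <- array(lab %in% keep, dim(mask))
  if (length(keep) != 1)
    warning(sprintf("expected a single cell, %d components survive the particle filter",
                    length(keep)))
  structure(list(voxels = out, cal = cal,
                 component_count = length(keep),
                 source_threshold = attr(mask, "threshold"),
                 voxel_count = sum(sizes[keep])),
            class = "mg_cell_mask")
}

#' @export
print.mg_cell_mask <- function(x, ...) {
  cat(sprintf("cell mask: %d voxels in %d component(s), threshold %s\n",
              x$voxel_count, x$component_count,
              if (is.null(x$source_threshold)) "unknown"
              else format(x$source_threshold)))
  invisible(x)
}

#' Crop a single-cell sub-volume around a seed point
#'
#' Seeded replacement for the interactive single-cell selection step: copies
#' a box of dimensions `box` centred on `seed_point`, clamping (with a
#' warning) when the box reaches the stack border. The crop origin is
#' recorded for traceability.
#'
#' @param x 3D array (or `mg_stack`).
#' @param seed_point integer voxel coordinate (row, col, z) inside the stack.
#' @param box integer crop dimensions (row, col, z).
#' @return cropped array with attribute `crop_origin` (1-based corner).
#' @export
extract_single_cell <- function(x, seed_point, box) {
  v <- as_voxels(x)
  d <- dim(v)
  stopifnot(length(seed_point) == 3, length(box) == 3)
  if (any(seed_point < 1 | seed_point > d))
    mg_stop("seed point outside stack", "mgmorph_bad_seed")
  lo <- pmax(1, round(seed_point - box / 2 + 0.5))
  hi <- lo + box - 1
  clamped <- any(hi > d) || any(lo < 1)
  hi <- pmin(hi, d)
  lo <- pmax(1, hi - box + 1)
  if (clamped) warning("crop box clamped to stack boundary")
  out <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  attr(out, "crop_origin") <- lo
  out
}

#' Full single-cell segmentation chain
#'
#' Composition of the segmentation stages: 8-bit conversion, maximum
#' projection, 0.5-fold scaling, Huang threshold on the scaled projection,
#' threshold application to the unmodified 3D image (mapped back through the
#' 8-bit conversion), and particle filtering.
#'
#' @param x 3D array or single-channel `mg_stack`.
#' @param cal [calibration()] of the input grid.
#' @param params [segmentation_params()].
#' @return `mg_cell_mask` (see [particle_filter()]) with the additional
#'   fields `threshold_8bit` and `source_range`.
#' @export
segment_cell <- function(x, cal = calibration(), params = segmentation_params()) {
  v <- as_voxels(x)
  if (inherits(x, "mg_stack")) cal <- x$cal
  v8 <- to_8bit(v)
  src <- attr(v8, "source_range")
  proj <- max_project(v8)
  if (params$scale_factor == 0.5) proj <- downscale_half(proj)
  t8 <- huang_threshold(hist256(round(proj)))
  bin <- apply_threshold_3d(v, t8, source_range = src)
  cm <- particle_filter(bin, params, cal)
  cm$threshold_8bit <- t8
  cm$source_range <- src
  cm
}
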