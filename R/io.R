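#' Calibrated voxel stack
#'
#' Container for a confocal z-stack: a 3D intensity array `[row, col, z]`
#' for one channel, or a 4D array `[row, col, z, channel]` for several.
#' Intensities are non-negative; `bit_depth` records the source depth.
#'
#' @param voxels numeric 3D or 4D array.
#' @param cal [calibration()] object.
#' @param bit_depth source bit depth (8 or 16).
#' @param channels optional character vector of channel names for 4D input.
#' @return an object of class `mg_stack`.
#' @export
voxel_stack <- function(voxels, cal = calibration(), bit_depth = 16, channels = NULL) {
  nd <- length(dim(voxels))
  if (!nd %in% c(3, 4))
    mg_stop("voxels must be a 3D or 4D array", "mgmorph_bad_stack")
  if (any(dim(voxels) <= 0))
    mg_stop("all stack dimensions must be positive", "mgmorph_bad_stack")
  if (min(voxels) < 0)
    mg_stop("stack intensities must be non-negative", "mgmorph_bad_stack")
  if (nd == 4) {
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(voxels)[4]))
    stopifnot(length(channels) == dim(voxels)[4])
    dimnames(voxels)[[4]] <- channels
  }
  structure(list(voxels = voxels, cal = cal, bit_depth = bit_depth),
            class = "mg_stack")
}

#' @export
print.mg_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("confocal stack: %s voxels, %d-bit\n",
              paste(d, collapse = " x "), x$bit_depth))
  print(x$cal)
  invisible(x)
}

# accept either an mg_stack or a bare array
as_voxels <- function(x) {
  if (inherits(x, "mg_stack")) x$voxels else x
}

# pull one channel as a 3D array
stack_channel <- function(x, channel) {
  v <- as_voxels(x)
  if (length(dim(v)) == 3) return(v)
  v[, , , channel, drop = TRUE]
}

#' Write / read calibrated multi-channel stacks as multi-page TIFF
#'
#' Stacks are written as 16-bit multi-page TIFFs, channel-fastest page order
#' (page = (z - 1) * n_channels + channel; the 5D convention TZCYX with a
#' single time point). Calibration, channel names and page layout travel in
#' a JSON sidecar (`<path>.json`), so a written stack reads back
#' identically; without a sidecar the acquisition defaults are assumed.
#'
#' @param stack an [voxel_stack()] object with integer intensities in
#'   `[0, 65535]`.
#' @param path output file.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `mg_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mg_stack"))
  v <- stack$voxels
  if (max(v) > 65535)
    mg_stop("stack intensities exceed 16-bit range", "mgmorph_bad_stack")
  if (length(dim(v)) == 3) dim(v) <- c(dim(v), 1L)
  nc <- dim(v)[4]
  nz <- dim(v)[3]
  channels <- dimnames(v)[[4]]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  pages <- vector("list", nz * nc)
  for (k in seq_len(nz)) {
    for (c in seq_len(nc)) {
      pages[[(k - 1) * nc + c]] <- v[, , k, c] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  jsonlite::write_json(list(mgmorph = 1, xy = stack$cal$xy_um_per_px,
                            z = stack$cal$z_um_per_voxel, nz = nz, nc = nc,
                            bit_depth = stack$bit_depth, channels = channels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- list(xy = 0.18, z = 0.5, nz = length(pages), nc = 1L, bit_depth = 16L,
               channels = NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(j)] <- j
    meta$nc <- as.integer(meta$nc); meta$nz <- as.integer(meta$nz)
  }
  d2 <- dim(pages[[1]])
  v <- array(0, c(d2[1], d2[2], meta$nz, meta$nc))
  for (k in seq_len(meta$nz))
    for (c in seq_len(meta$nc))
      v[, , k, c] <- round(pages[[(k - 1) * meta$nc + c]] * 65535)
  if (meta$nc == 1) {
    dim(v) <- dim(v)[1:3]
  } else {
    dimnames(v)[[4]] <- meta$channels
  }
  voxel_stack(v, calibration(meta$xy, meta$z), bit_depth = meta$bit_depth,
              channels = meta$channels)
}

#' Write / read a per-cell metric table as CSV
#'
#' Round-trip-safe CSV I/O for morphometry and puncta tables (full double
#' precision, no row names).
#'
#' @param records data.frame of per-cell records.
#' @param path CSV file path.
#' @export
write_records <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
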