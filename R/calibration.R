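#' Voxel calibration
#'
#' Physical voxel size of a confocal stack. The default matches the
#' acquisition geometry of the imaging protocol this package reproduces
#' (63x objective: 0.18 um/px laterally, 0.5 um z-step). The single-cell
#' analysis stage of the original toolbox worked on a half-scaled grid with
#' 0.3608 um/px, available as [analysis_calibration()].
#'
#' @param xy_um_per_px lateral pixel size in micrometres per pixel (> 0).
#' @param z_um_per_voxel axial step in micrometres per voxel (> 0).
#' @return an object of class `mg_calibration` with fields `xy_um_per_px`
#'   and `z_um_per_voxel`.
#' @export
#' @examples
#' calibration()                 # acquisition grid
#' analysis_calibration()        # half-scaled analysis grid
calibration <- function(xy_um_per_px = 0.18, z_um_per_voxel = 0.5) {
  if (!is.numeric(xy_um_per_px) || length(xy_um_per_px) != 1 || xy_um_per_px <= 0)
    mg_stop("xy_um_per_px must be a single positive number", "mgmorph_bad_calibration")
  if (!is.numeric(z_um_per_voxel) || length(z_um_per_voxel) != 1 || z_um_per_voxel <= 0)
    mg_stop("z_um_per_voxel must be a single positive number", "mgmorph_bad_calibration")
  structure(list(xy_um_per_px = xy_um_per_px, z_um_per_voxel = z_um_per_voxel),
            class = "mg_calibration")
}

#' @rdname calibration
#' @export
analysis_calibration <- function() calibration(0.3608, 0.5)

#' @export
print.mg_calibration <- function(x, ...) {
  cat(sprintf("voxel calibration: %.4f um/px (xy), %.4f um/voxel (z)\n",
              x$xy_um_per_px, x$z_um_per_voxel))
  invisible(x)
}

# voxel volume in um^3
voxel_volume <- function(cal) cal$xy_um_per_px^2 * cal$z_um_per_voxel

# spacing vector (x, y, z) in um
cal_spacing <- function(cal) c(cal$xy_um_per_px, cal$xy_um_per_px, cal$z_um_per_voxel)
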