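# Soma ROI polygons: constructor, pixel rasterization, and I/O in the
# de-facto standard ImageJ .roi format plus a plain JSON schema.

#' Soma region of interest
#'
#' A simple (non-self-intersecting) 2D polygon delineating one soma, in
#' pixel coordinates. Pixel `(row r, col c)` has its centre at
#' `(x = c - 0.5, y = r - 0.5)`; polygon vertices are `(x, y)` pairs in
#' those units, as drawn by ImageJ's polygon-selection tool.
#'
#' @param vertices numeric matrix (n x 2) of `(x, y)` vertices, n >= 3.
#' @param cal [calibration()] giving the pixel size.
#' @param mouse,cell optional identifiers.
#' @return object of class `mg_soma_roi`.
#' @export
soma_roi <- function(vertices, cal = calibration(), mouse = NA_character_,
                     cell = NA_character_) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (abs(polygon_area_px(vertices)) <= 0)
    mg_stop("polygon has zero area", "mgmorph_bad_roi")
  if (polygon_self_intersects(vertices))
    mg_stop("polygon is self-intersecting", "mgmorph_bad_roi")
  structure(list(vertices = vertices, cal = cal,
                 mouse = as.character(mouse), cell = as.character(cell)),
            class = "mg_soma_roi")
}

#' @export
print.mg_soma_roi <- function(x, ...) {
  cat(sprintf("soma ROI: %d vertices, area %.2f um^2 (mouse %s, cell %s)\n",
              nrow(x$vertices), roi_area_um2(x), x$mouse, x$cell))
  invisible(x)
}

# signed shoelace area in px^2
polygon_area_px <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# O(n^2) segment-intersection test, ignoring shared endpoints
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (a == 1 && b == n) next    # adjacent through the closure
      d1 <- cross2(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 1], seg[b, 2])
      d2 <- cross2(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 3], seg[b, 4])
      d3 <- cross2(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 1], seg[a, 2])
      d4 <- cross2(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 3], seg[a, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area of an ROI in square micrometres
#'
#' @param roi [soma_roi()].
#' @return area in um^2 (shoelace area times `xy_um_per_px^2`).
#' @export
roi_area_um2 <- function(roi) {
  abs(polygon_area_px(roi$vertices)) * roi$cal$xy_um_per_px^2
}

#' Rasterize an ROI onto a pixel grid
#'
#' A pixel belongs to the ROI iff its centre falls inside the polygon
#' (even-odd rule). Uses `mgcv::in.out` for the point-in-polygon test.
#'
#' @param roi [soma_roi()].
#' @param dim image dimensions `(rows, cols)`.
#' @return logical matrix.
#' @export
roi_pixel_mask <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  v <- roi$vertices
  bnd <- rbind(v, v[1, ])
  # restrict the test to the polygon's bounding box
  cc <- max(1, floor(min(v[, 1]) + 0.5)):min(nc, ceiling(max(v[, 1]) + 0.5))
  rr <- max(1, floor(min(v[, 2]) + 0.5)):min(nr, ceiling(max(v[, 2]) + 0.5))
  grid <- expand.grid(r = rr, c = cc)
  inside <- mgcv::in.out(bnd, cbind(grid$c - 0.5, grid$r - 0.5))
  out <- matrix(FALSE, nr, nc)
  out[cbind(grid$r, grid$c)] <- inside
  out
}

#' Read and write ImageJ .roi polygon files
#'
#' Minimal reader/writer for the polygon variant of the binary ImageJ ROI
#' format ("Iout" magic, big-endian, integer vertex coordinates), enough to
#' exchange manually drawn soma outlines with ImageJ/Fiji.
#'
#' @param path `.roi` file.
#' @param roi [soma_roi()] with (near-)integer vertices.
#' @param cal [calibration()] to attach on read.
#' @return `read_ij_roi` returns an [soma_roi()]; `write_ij_roi` returns
#'   `path` invisibly.
#' @export
read_ij_roi <- function(path, cal = calibration()) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:4]) != "Iout")
    mg_stop("not an ImageJ ROI file", "mgmorph_bad_roi")
  be_short <- function(off) {      # 0-based offset, signed 16-bit big-endian
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big", signed = TRUE)
  }
  type <- as.integer(raw[7])
  if (type != 0L)
    mg_stop("only polygon ROIs are supported", "mgmorph_bad_roi")
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16)
  xs <- vapply(seq_len(n), function(i) be_short(64 + 2 * (i - 1)), integer(1)) + left
  ys <- vapply(seq_len(n), function(i) be_short(64 + 2 * n + 2 * (i - 1)), integer(1)) + top
  soma_roi(cbind(xs, ys), cal = cal)
}

#' @rdname read_ij_roi
#' @export
write_ij_roi <- function(roi, path) {
  v <- round(roi$vertices)
  n <- nrow(v)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(as.integer(c(227, 0)), con, size = 2, endian = "big")  # version, type=polygon
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                                     # pad header to 64 bytes
  writeBin(as.integer(v[, 1] - left), con, size = 2, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2, endian = "big")
  invisible(path)
}

#' Read and write soma ROIs as JSON
#'
#' Plain-text alternative to the binary ImageJ format: an object with
#' `vertices` (n x 2), `xy_um_per_px`, `z_um_per_voxel`, `mouse`, `cell`.
#'
#' @param roi [soma_roi()].
#' @param path JSON file.
#' @return `read_roi_json` returns an [soma_roi()].
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(list(vertices = unname(roi$vertices),
                            xy_um_per_px = roi$cal$xy_um_per_px,
                            z_um_per_voxel = roi$cal$z_um_per_voxel,
                            mouse = roi$mouse, cell = roi$cell),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  soma_roi(j$vertices, calibration(j$xy_um_per_px, j$z_um_per_voxel),
           mouse = j$mouse, cell = j$cell)
}
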