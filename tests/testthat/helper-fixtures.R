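# Shared fixture builders. Everything is generated in code at test time;
# heavier shared fixtures are memoized for the session.

empty_segs <- function() {
  data.frame(parent = integer(), x0 = numeric(), y0 = numeric(),
             z0 = numeric(), x1 = numeric(), y1 = numeric(), z1 = numeric(),
             radius_um = numeric())
}

# solid sphere spec of radius r at `center`
sphere_spec <- function(r, center = c(16, 16, 16)) {
  cell_spec(center, rep(r, 3), empty_segs())
}

# 4-armed planar cross; `stretch` lengthens the +x arm
cross_spec <- function(center = c(20, 20, 12), arm = 12, r = 0.9, stretch = 1) {
  segs <- data.frame(
    parent = 0,
    x0 = center[1], y0 = center[2], z0 = center[3],
    x1 = center[1] + c(arm * stretch, -arm, 0, 0),
    y1 = center[2] + c(0, 0, arm, -arm),
    z1 = center[3],
    radius_um = r)
  cell_spec(center, c(2.6, 2.6, 2.2), segs)
}

# a digitized ball as a plain logical array (isotropic voxel grid)
ball_mask <- function(r_vox, dim = rep(2 * r_vox + 9, 3)) {
  cx <- (dim + 1) / 2
  co <- arrayInd(seq_len(prod(dim)), dim)
  array(((co[, 1] - cx[1])^2 + (co[, 2] - cx[2])^2 + (co[, 3] - cx[3])^2)
        <= r_vox^2, dim)
}

# solid cuboid mask with the given voxel side lengths, padded by `pad`
cuboid_mask <- function(sides, pad = 4) {
  dim <- sides + 2 * pad
  m <- array(FALSE, dim)
  m[pad + seq_len(sides[1]), pad + seq_len(sides[2]), pad + seq_len(sides[3])] <- TRUE
  m
}

# memoized default-parameter cell + raster + noisy render
.fixture_env <- new.env(parent = emptyenv())
default_cell <- function(seed = 11) {
  key <- paste0("cell", seed)
  if (is.null(.fixture_env[[key]])) {
    g <- generate_cell(cell_params(), seed = seed, center_um = c(20, 20, 12))
    mask <- rasterize_cell(g$spec, calibration(), c(224L, 224L, 48L))
    .fixture_env[[key]] <- list(gen = g, mask = mask)
  }
  .fixture_env[[key]]
}

# independent brute-force implementation of the Huang fuzzy-entropy
# objective, evaluated exhaustively over all candidate levels
huang_bruteforce <- function(counts) {
  occ <- which(counts > 0) - 1L
  g <- 0:255
  C <- max(occ) - min(occ)
  best <- Inf; bt <- NA_integer_
  for (t in min(occ):(max(occ) - 1L)) {
    lo <- g <= t
    n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
    mu0 <- sum(counts[lo] * g[lo]) / n0
    mu1 <- sum(counts[!lo] * g[!lo]) / n1
    u <- ifelse(lo, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    s <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    f <- sum(counts * s)
    if (f < best - 1e-12) { best <- f; bt <- t }
  }
  bt
}

# random sparse-ish 256-bin histogram with at least two occupied bins
random_histogram <- function() {
  repeat {
    k <- sample(2:40, 1)
    counts <- integer(256)
    counts[sample(256, k)] <- rpois(k, 200) + 1L
    if (sum(counts > 0) >= 2) return(counts)
  }
}
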