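# Synthetic confocal stacks of branched microglia-like cells with exact
# ground truth: the oracle for every downstream stage.

#' Generator parameters for synthetic microglia-like cells
#'
#' Ranges chosen to emulate ramified hippocampal microglia at the
#' acquisition geometry of the reproduced protocol: a soma of a few
#' micrometres with several primary processes that may bifurcate once.
#'
#' @param n_primary integer range (min, max) of primary processes (1-6).
#' @param primary_length_um length range of primary processes, measured from
#'   the soma centre, um.
#' @param child_length_um length range of daughter branches, um.
#' @param p_split probability that a primary process bifurcates at its tip.
#' @param radius_um tube radius range, um (>= 2 px at the acquisition grid
#'   so rasterization cannot disconnect).
#' @param soma_semiaxes_um soma ellipsoid semi-axes, um.
#' @param asymmetry_strength >= 0; 0 gives isotropic process directions,
#'   larger values bias processes toward one hemisphere (polarized cells).
#' @param min_separation_um minimum clearance between non-adjacent branch
#'   axes so branches never fuse (keeps skeleton topology identifiable).
#' @param z_flatten factor (0-1] compressing the axial component of process
#'   directions: arbors are flattened so whole cells fit a ~24-30 um stack,
#'   as single-cell fixtures must.
#' @param max_extent_um,max_z_extent_um hard bounds on the lateral/axial
#'   half-extent of the cell (including tube radius) from the soma centre;
#'   layouts exceeding them are resampled.
#' @return list of class `mg_cell_params`.
#' @export
cell_params <- function(n_primary = c(4L, 6L),
                        primary_length_um = c(8, 13),
                        child_length_um = c(5, 8),
                        p_split = 0.5,
                        radius_um = c(0.9, 1.2),
                        soma_semiaxes_um = c(3.4, 3.0, 2.6),
                        asymmetry_strength = 0,
                        min_separation_um = 3.0,
                        z_flatten = 0.5,
                        max_extent_um = 19,
                        max_z_extent_um = 9.5) {
  if (max(n_primary) < 1)
    mg_stop("degenerate parameters: at least one primary process is required",
            "mgmorph_bad_params")
  stopifnot(min(n_primary) >= 1, max(n_primary) <= 6,
            all(primary_length_um > 0), all(child_length_um > 0),
            p_split >= 0, p_split <= 1,
            all(radius_um >= 2 * 0.18), length(soma_semiaxes_um) == 3,
            all(soma_semiaxes_um > 0), asymmetry_strength >= 0)
  structure(list(n_primary = as.integer(n_primary),
                 primary_length_um = primary_length_um,
                 child_length_um = child_length_um,
                 p_split = p_split,
                 radius_um = radius_um,
                 soma_semiaxes_um = soma_semiaxes_um,
                 asymmetry_strength = asymmetry_strength,
                 min_separation_um = min_separation_um,
                 z_flatten = z_flatten,
                 max_extent_um = max_extent_um,
                 max_z_extent_um = max_z_extent_um),
            class = "mg_cell_params")
}

#' Explicit cell specification
#'
#' Geometric description of one synthetic cell: a soma ellipsoid plus a tree
#' of capsule (tube) segments. Primary segments start at the soma centre so
#' the skeleton-based tree length is defined on the same construct the
#' measurement produces; the tree must be a single connected component.
#'
#' @param soma_center_um,soma_semiaxes_um soma ellipsoid, um.
#' @param segments data.frame with columns `parent` (0 for primary
#'   processes, else row index of the parent segment), `x0,y0,z0,x1,y1,z1`
#'   (um) and `radius_um`.
#' @return object of class `mg_cell_spec`.
#' @export
cell_spec <- function(soma_center_um, soma_semiaxes_um, segments) {
  stopifnot(length(soma_center_um) == 3, length(soma_semiaxes_um) == 3,
            all(c("parent", "x0", "y0", "z0", "x1", "y1", "z1", "radius_um")
                %in% names(segments)))
  if (nrow(segments) > 0) {
    for (s in seq_len(nrow(segments))) {
      p <- segments$parent[s]
      if (p == 0) {
        start_ok <- all(abs(c(segments$x0[s], segments$y0[s], segments$z0[s]) -
                            soma_center_um) < 1e-9)
        if (!start_ok)
          mg_stop("primary segments must start at the soma centre", "mgmorph_bad_spec")
      } else {
        pe <- c(segments$x1[p], segments$y1[p], segments$z1[p])
        if (!all(abs(c(segments$x0[s], segments$y0[s], segments$z0[s]) - pe) < 1e-9))
          mg_stop("child segments must start at the parent tip", "mgmorph_bad_spec")
      }
    }
  }
  structure(list(soma_center_um = soma_center_um,
                 soma_semiaxes_um = soma_semiaxes_um,
                 segments = segments),
            class = "mg_cell_spec")
}

seg_length <- function(segments) {
  sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
       (segments$z1 - segments$z0)^2)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# random unit vector, optionally biased toward +x and flattened in z
rand_dir <- function(bias = 0, z_flatten = 1) {
  unit3((rnorm(3) + c(bias, 0, 0)) * c(1, 1, z_flatten))
}

# rotate unit vector `d` by angle `ang` toward a random perpendicular
tilt_dir <- function(d, ang) {
  p <- rnorm(3)
  p <- p - sum(p * d) * d
  p <- unit3(p)
  unit3(cos(ang) * d + sin(ang) * p)
}

#' Generate a random branched cell with ground truth
#'
#' Draws soma and process geometry from `params` (deterministically for a
#' fixed seed), enforcing pairwise angular separation of primary processes
#' and a minimum clearance between non-adjacent branches, then computes the
#' exact metrics of the resulting tube/ellipsoid union (see
#' [cell_ground_truth()]).
#'
#' @param params [cell_params()].
#' @param seed integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @param center_um cell position (soma centre), um.
#' @return list with `spec` ([cell_spec()]) and `truth` (one-row
#'   `data.frame`, see [cell_ground_truth()]).
#' @export
generate_cell <- function(params = cell_params(), seed = 1,
                          center_um = c(20, 20, 12)) {
  spec <- with_seed(seed, {
    attempt <- 0
    repeat {
      attempt <- attempt + 1
      if (attempt > 200)
        mg_stop("could not place non-fusing branches within retry budget",
                "mgmorph_placement_failure")
      sp <- try_generate_spec(params, center_um)
      if (!is.null(sp)) break
    }
    sp
  })
  truth <- cell_ground_truth(spec, seed = (as.numeric(seed) + 7919) %% 2147483647)
  list(spec = spec, truth = truth)
}

# one attempt at a geometric layout; NULL if the clearance check fails
try_generate_spec <- function(params, center_um) {
  np <- if (params$n_primary[1] == params$n_primary[2]) params$n_primary[1]
        else sample(params$n_primary[1]:params$n_primary[2], 1)
  min_ang <- 0.7                         # ~40 deg between primary processes
  dirs <- list()
  guard <- 0
  while (length(dirs) < np) {
    guard <- guard + 1
    if (guard > 500) return(NULL)
    d <- rand_dir(params$asymmetry_strength, params$z_flatten)
    ok <- all(vapply(dirs, function(e) acos(pmin(1, sum(d * e))) > min_ang,
                     logical(1)))
    if (ok) dirs[[length(dirs) + 1]] <- d
  }
  segs <- data.frame(parent = integer(), x0 = numeric(), y0 = numeric(),
                     z0 = numeric(), x1 = numeric(), y1 = numeric(),
                     z1 = numeric(), radius_um = numeric())
  for (i in seq_len(np)) {
    L <- runif(1, params$primary_length_um[1], params$primary_length_um[2])
    r <- runif(1, params$radius_um[1], params$radius_um[2])
    tip <- center_um + L * dirs[[i]]
    segs[nrow(segs) + 1, ] <- c(0, center_um, tip, r)
    if (runif(1) < params$p_split) {
      parent_row <- nrow(segs)
      a1 <- runif(1, 0.45, 0.85)          # ~25-50 deg off the parent
      a2 <- runif(1, 0.45, 0.85)
      d1 <- tilt_dir(dirs[[i]], a1)
      d2 <- tilt_dir(dirs[[i]], a2)
      guard2 <- 0
      while (acos(pmin(1, sum(d1 * d2))) < 0.6 && guard2 < 100) {
        d2 <- tilt_dir(dirs[[i]], runif(1, 0.45, 0.85))
        guard2 <- guard2 + 1
      }
      for (d in list(d1, d2)) {
        Lc <- runif(1, params$child_length_um[1], params$child_length_um[2])
        segs[nrow(segs) + 1, ] <- c(parent_row, tip, tip + Lc * d, 0.8 * r)
      }
    }
  }
  # cell-to-cell variability on the soma: mild lognormal size and shape
  # jitter, kept small enough that group truth means track requested
  # effect sizes at cohort sample sizes
  sax <- params$soma_semiaxes_um * exp(rnorm(1, 0, 0.03)) * exp(rnorm(3, 0, 0.02))
  if (!branches_clear(segs, params$min_separation_um)) return(NULL)
  # enforce the extent bounds (including tube radius) so cells fit a stack
  ends <- rbind(as.matrix(segs[, c("x0", "y0", "z0")]),
                as.matrix(segs[, c("x1", "y1", "z1")]))
  reach <- abs(sweep(ends, 2, center_um)) + rep(segs$radius_um, 2)
  if (max(reach[, 1:2], sax[1:2]) > params$max_extent_um)
    return(NULL)
  if (max(reach[, 3], sax[3]) > params$max_z_extent_um)
    return(NULL)
  cell_spec(center_um, sax, segs)
}

# minimum clearance between non-adjacent segment axes, sampled along each axis
branches_clear <- function(segs, min_sep) {
  n <- nrow(segs)
  if (n < 2) return(TRUE)
  sm <- as.matrix(segs[, c("x0", "y0", "z0", "x1", "y1", "z1")])
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      adjacent <- segs$parent[b] == a || segs$parent[a] == b ||
        (segs$parent[a] == 0 && segs$parent[b] == 0) &&
          all(sm[a, 1:3] == sm[b, 1:3]) ||
        (segs$parent[a] == segs$parent[b])
      req <- segs$radius_um[a] + segs$radius_um[b] + min_sep
      ts <- seq(if (adjacent) 0.35 else 0, 1, length.out = 14)
      pts <- cbind(sm[b, 1] + ts * (sm[b, 4] - sm[b, 1]),
                   sm[b, 2] + ts * (sm[b, 5] - sm[b, 2]),
                   sm[b, 3] + ts * (sm[b, 6] - sm[b, 3]))
      dmin <- min(vapply(seq_len(nrow(pts)), function(q)
        cpp_seg_dist(sm[a, , drop = FALSE], pts[q, ]), numeric(1)))
      if (adjacent) {
        # shared endpoint: only require that the far parts stay clear
        if (dmin < 0) return(FALSE)
      } else if (dmin < req) return(FALSE)
    }
  }
  TRUE
}

# Thomsen approximation to the ellipsoid surface area (error < 1.1%)
ellipsoid_area <- function(s) {
  p <- 1.6075
  4 * pi * ((s[1]^p * s[2]^p + s[1]^p * s[3]^p + s[2]^p * s[3]^p) / 3)^(1 / p)
}

#' Exact metrics of a synthetic cell
#'
#' Computes the ground-truth metric vector of a [cell_spec()] from the
#' tube/ellipsoid union geometry. Volume and centre of mass use Monte-Carlo
#' integration with overlap rejection (points falling in an
#' already-counted primitive are discarded); surface area uses dense
#' area-uniform surface sampling with rejection of samples lying inside any
#' other primitive. With the default sample counts both are accurate to
#' about 1-2% (documented tolerance 2%). Topological quantities are exact:
#' `branch_count` is the number of tube segments, `tree_length` the sum of
#' their lengths (primaries measured from the soma centre, matching the
#' skeleton-based measurement), `soma_area` the analytic mid-plane
#' cross-section `pi * a * b`.
#'
#' @param spec [cell_spec()].
#' @param seed seed for the Monte-Carlo integrals.
#' @param n_samples samples per primitive and integral.
#' @return one-row `data.frame`: `volume_um3`, `surface_um2`,
#'   `branch_count`, `tree_length_um`, `average_branch_length_um`,
#'   `soma_area_um2`, `com_offset_um`, `puncta_count`,
#'   `puncta_area_fraction` (the last two `NA` until puncta are planted).
#' @export
cell_ground_truth <- function(spec, seed = 1, n_samples = 8000) {
  segs <- spec$segments
  c0 <- spec$soma_center_um
  ax <- spec$soma_semiaxes_um
  n_seg <- nrow(segs)
  sm <- if (n_seg) as.matrix(segs[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius_um")])
        else matrix(numeric(), 0, 7)
  lens <- if (n_seg) seg_length(segs) else numeric(0)

  ell_mat <- matrix(c(c0, ax), 1)
  no_ell <- matrix(numeric(), 0, 6)
  no_cap <- matrix(numeric(), 0, 7)
  cap_rows <- function(rows) {
    if (length(rows)) sm[rows, , drop = FALSE] else no_cap
  }

  res <- with_seed(seed, {
    vol_total <- 0
    com_acc <- c(0, 0, 0)
    surf_total <- 0
    for (m in 0:n_seg) {
      if (m == 0) {
        V <- 4 / 3 * pi * prod(ax)
        A <- ellipsoid_area(ax)
        sample_inside <- function(n) {
          u <- matrix(rnorm(3 * n), n)
          u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
          sweep(u %*% diag(ax), 2, c0, "+")
        }
        sample_surface <- function(n) {
          out <- matrix(NA_real_, 0, 3)
          gmax <- max(ax[2] * ax[3], ax[1] * ax[3], ax[1] * ax[2])
          while (nrow(out) < n) {
            u <- matrix(rnorm(3 * n), n)
            u <- u / sqrt(rowSums(u^2))
            g <- sqrt((u[, 1] * ax[2] * ax[3])^2 + (u[, 2] * ax[1] * ax[3])^2 +
                      (u[, 3] * ax[1] * ax[2])^2)
            keep <- runif(n) < g / gmax
            out <- rbind(out, sweep(u[keep, , drop = FALSE] %*% diag(ax), 2, c0, "+"))
          }
          out[seq_len(n), , drop = FALSE]
        }
      } else {
        r <- sm[m, 7]; L <- lens[m]
        p0 <- sm[m, 1:3]; p1 <- sm[m, 4:6]
        axis <- if (L > 0) (p1 - p0) / L else c(0, 0, 1)
        V <- pi * r^2 * L + 4 / 3 * pi * r^3
        A <- 2 * pi * r * L + 4 * pi * r^2
        # orthonormal frame around the axis
        e1 <- unit3(if (abs(axis[1]) < 0.9) pracma_cross(axis, c(1, 0, 0))
                    else pracma_cross(axis, c(0, 1, 0)))
        e2 <- pracma_cross(axis, e1)
        cyl_pts <- function(n, rad) {
          t <- runif(n, 0, L)
          th <- runif(n, 0, 2 * pi)
          sweep(outer(t, axis) + outer(rad * cos(th), e1) +
                  outer(rad * sin(th), e2), 2, p0, "+")
        }
        cap_pts <- function(b) {
          # hemisphere offsets attach to the tip they point toward
          hi <- as.vector(b %*% axis) >= 0
          ends <- matrix(p0, nrow(b), 3, byrow = TRUE)
          ends[hi, ] <- matrix(p1, sum(hi), 3, byrow = TRUE)
          ends + b
        }
        sample_inside <- function(n) {
          in_cyl <- runif(n) < (pi * r^2 * L) / V
          b <- matrix(rnorm(3 * n), n)
          b <- b / sqrt(rowSums(b^2)) * (r * runif(n)^(1 / 3))
          pts <- cyl_pts(n, r * sqrt(runif(n)))
          pts[!in_cyl, ] <- cap_pts(b[!in_cyl, , drop = FALSE])
          pts
        }
        sample_surface <- function(n) {
          on_cyl <- runif(n) < (2 * pi * r * L) / A
          u <- matrix(rnorm(3 * n), n)
          u <- u / sqrt(rowSums(u^2)) * r
          pts <- cyl_pts(n, rep(r, n))
          pts[!on_cyl, ] <- cap_pts(u[!on_cyl, , drop = FALSE])
          pts
        }
      }
      pts <- sample_inside(n_samples)
      # overlap rejection: count each point once, in its first primitive
      keep <- !cpp_inside_any(pts, if (m >= 1) ell_mat else no_ell,
                              cap_rows(seq_len(max(0, m - 1))))
      w <- V / n_samples
      vol_total <- vol_total + sum(keep) * w
      if (any(keep)) com_acc <- com_acc + colSums(pts[keep, , drop = FALSE]) * w
      spts <- sample_surface(n_samples)
      skeep <- !cpp_inside_any(spts, if (m == 0) no_ell else ell_mat,
                               cap_rows(setdiff(seq_len(n_seg), m)))
      surf_total <- surf_total + A * sum(skeep) / n_samples
    }
    list(vol = vol_total, com = com_acc / vol_total, surf = surf_total)
  })

  bc <- n_seg
  tl <- sum(lens)
  data.frame(volume_um3 = res$vol,
             surface_um2 = res$surf,
             branch_count = as.integer(bc),
             tree_length_um = tl,
             average_branch_length_um = if (bc > 0) tl / bc else 0,
             soma_area_um2 = pi * ax[1] * ax[2],
             com_offset_um = sqrt(sum((res$com - c0)^2)),
             puncta_count = NA_integer_,
             puncta_area_fraction = NA_real_)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Rasterize a cell specification onto a voxel grid
#'
#' Voxelizes the soma ellipsoid and capsule segments (a voxel is foreground
#' iff its centre lies inside the union). The cell must fit inside the
#' volume with a two-voxel margin: boundary-touching cells are rejected, and
#' the result is verified to be a single 26-connected component.
#'
#' @param spec [cell_spec()].
#' @param cal [calibration()].
#' @param shape integer voxel dimensions (rows, cols, z).
#' @return logical 3D array.
#' @export
rasterize_cell <- function(spec, cal = calibration(), shape = c(224L, 224L, 48L)) {
  sp <- cal_spacing(cal)
  caps <- if (nrow(spec$segments))
    as.matrix(spec$segments[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius_um")])
  else matrix(numeric(), 0, 7)
  ell <- matrix(c(spec$soma_center_um, spec$soma_semiaxes_um), 1)
  mask <- cpp_rasterize(as.integer(shape), sp, caps, ell)
  mask <- array(mask, shape)
  occ <- which(mask)
  if (length(occ) == 0)
    mg_stop("rasterization produced an empty mask", "mgmorph_bad_spec")
  co <- arrayInd(occ, shape)
  if (any(apply(co, 2, min) <= 2) || any(apply(co, 2, max) >= shape - 2))
    mg_stop("cell clipped by the volume boundary (needs a 2-voxel margin)",
            "mgmorph_cell_clipped")
  ncomp <- attr(cpp_label3d(mask, dim(mask), 26L), "n_components")
  if (ncomp != 1)
    mg_stop("rasterized cell is not a single 26-connected component",
            "mgmorph_bad_spec")
  mask
}

#' Confocal noise model
#'
#' @param psf_sigma_xy,psf_sigma_z Gaussian point-spread sigma, voxels.
#' @param background,foreground mean photon counts outside/inside the cell
#'   (foreground > background >= 0).
#' @param shot_noise apply Poisson shot noise.
#' @param seed integer seed for the noise stream.
#' @return list of class `mg_noise_model`.
#' @export
noise_model <- function(psf_sigma_xy = 1.0, psf_sigma_z = 0.6,
                        background = 20, foreground = 120,
                        shot_noise = TRUE, seed = 1L) {
  stopifnot(background >= 0, foreground > background,
            psf_sigma_xy >= 0, psf_sigma_z >= 0)
  structure(list(psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 background = background, foreground = foreground,
                 shot_noise = shot_noise, seed = as.integer(seed)),
            class = "mg_noise_model")
}

#' Render binary masks into a noisy intensity stack
#'
#' Per channel: `intensity = background + (foreground - background) * mask`,
#' optionally convolved with a Gaussian point-spread function and corrupted
#' by Poisson shot noise. Bit-identical for a fixed noise seed.
#'
#' @param masks a logical 3D array or a named list of such arrays (one per
#'   channel), all of the same shape.
#' @param noise [noise_model()].
#' @param cal [calibration()] recorded on the resulting stack.
#' @return an [voxel_stack()] (3D for one channel, 4D otherwise).
#' @export
render_stack <- function(masks, noise = noise_model(), cal = calibration()) {
  if (!is.list(masks)) masks <- list(ch1 = masks)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d))
      mg_stop("channel masks must share one shape", "mgmorph_bad_stack")
  chans <- with_seed(noise$seed, lapply(masks, function(m) {
    f <- noise$background + (noise$foreground - noise$background) *
      array(as.numeric(m), d)
    if (noise$psf_sigma_xy > 0 || noise$psf_sigma_z > 0)
      f <- cpp_gauss3d(f, d, c(noise$psf_sigma_xy, noise$psf_sigma_xy,
                               noise$psf_sigma_z))
    if (noise$shot_noise) f <- array(rpois(length(f), f), d)
    array(round(f), d)
  }))
  if (length(chans) == 1) return(voxel_stack(chans[[1]], cal))
  v <- array(0, c(d, length(chans)))
  for (c in seq_along(chans)) v[, , , c] <- chans[[c]]
  voxel_stack(v, cal, channels = names(chans))
}

#' Plant non-overlapping puncta inside a region
#'
#' Places `count` spheres with radii drawn from `radius_um` fully inside
#' `region`, pairwise non-touching in the xy-projection (hence also in 3D
#' and after projection), and returns the binary channel plus the exact
#' ground truth: the count and the area fraction of the puncta projection
#' within the region projection — the same construct the downstream
#' quantification measures.
#'
#' @param region logical 3D array (e.g. a soma mask).
#' @param count number of puncta (>= 0).
#' @param radius_um length-2 radius range, um.
#' @param cal [calibration()].
#' @param seed integer seed.
#' @param max_tries placement retry budget per punctum.
#' @return list with `mask` (logical 3D array), `count`,
#'   `area_fraction` (percent of the region projection covered).
#' @export
generate_puncta <- function(region, count, radius_um = c(0.5, 0.8),
                            cal = calibration(), seed = 1, max_tries = 2000) {
  stopifnot(is.logical(region), length(dim(region)) == 3, count >= 0)
  d <- dim(region)
  sp <- cal_spacing(cal)
  if (count == 0) {
    return(list(mask = array(FALSE, d), count = 0L, area_fraction = 0))
  }
  placed <- with_seed(seed, {
    centers <- matrix(numeric(), 0, 3)
    radii <- numeric(0)
    cand <- which(region)
    co <- arrayInd(cand, d)
    pos <- cbind((co[, 1] - 0.5) * sp[1], (co[, 2] - 0.5) * sp[2],
                 (co[, 3] - 0.5) * sp[3])
    tries <- 0
    while (length(radii) < count) {
      tries <- tries + 1
      if (tries > max_tries)
        mg_stop("puncta placement failed within the retry budget",
                "mgmorph_placement_failure")
      r <- runif(1, radius_um[1], radius_um[2])
      q <- sample(nrow(pos), 1)
      p <- pos[q, ]
      # sphere fully inside the region: all voxel centres within r of p are in region
      box <- ceiling(r / sp) + 1L
      i0 <- pmax(1, co[q, ] - box); i1 <- pmin(d, co[q, ] + box)
      sub <- region[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      sco <- arrayInd(seq_along(sub), dim(sub))
      spos <- cbind((sco[, 1] + i0[1] - 1.5) * sp[1],
                    (sco[, 2] + i0[2] - 1.5) * sp[2],
                    (sco[, 3] + i0[3] - 1.5) * sp[3])
      within <- sqrt(rowSums(sweep(spos, 2, p)^2)) <= r + max(sp)
      if (any(within & !as.vector(sub))) next
      # non-touching in the xy-projection, with a one-voxel guard band
      if (length(radii)) {
        dxy <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
        if (any(dxy <= radii + r + 2 * max(sp[1:2]))) next
      }
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }
    list(centers = centers, radii = radii)
  })
  ell <- cbind(placed$centers, placed$radii, placed$radii, placed$radii)
  mask <- array(cpp_rasterize(as.integer(d), sp, matrix(numeric(), 0, 7), ell), d)
  lab <- cpp_label3d(mask, d, 26L)
  if (attr(lab, "n_components") != count)
    mg_stop("puncta rasterization merged or lost components", "mgmorph_placement_failure")
  proj <- apply(mask, c(1, 2), any)
  rproj <- apply(region, c(1, 2), any)
  list(mask = mask, count = as.integer(count),
       area_fraction = 100 * sum(proj & rproj) / sum(rproj))
}

# derive a per-cell RNG stream from a root seed (documented splitting rule)
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) * 1000003 + index * 7907) %% 2147483647)
}

#' Generate an on-disk synthetic cohort
#'
#' Writes a directory of single-cell TIFF stacks with known ground truth:
#' `design.yaml`, `truth_cells.csv`, `truth_cohort.csv` (per-group truth
#' summaries), and per cell `group_<g>/mouse_<m>/cell_<c>.tif` plus a soma
#' ROI polygon (`*_soma.json`, the mid-plane soma ellipse). Per-group effect
#' sizes act multiplicatively on the generative parameters: `soma_size`
#' scales the soma cross-section area, `tree_length` scales process
#' lengths, `radius` scales tube radii. One root seed drives everything;
#' per-cell streams are split deterministically, so regeneration is
#' hash-identical.
#'
#' @param design list with `groups` (list of `list(name, n_mice, effects)`),
#'   `cells_per_mouse`, and optionally `params` ([cell_params()]), `noise`
#'   ([noise_model()]), `cal`, `shape`.
#' @param out_dir output directory (created; must be writable).
#' @param seed root integer seed.
#' @return invisibly, the truth-cells data.frame (also written as CSV).
#' @export
generate_cohort <- function(design, out_dir, seed = 1) {
  stopifnot(length(design$groups) >= 1)
  for (g in design$groups) stopifnot(g$n_mice >= 2)
  params <- design$params %||% cell_params()
  noise <- design$noise %||% noise_model()
  cal <- design$cal %||% calibration()
  shape <- design$shape %||% c(224L, 224L, 48L)
  cpm <- design$cells_per_mouse %||% 4L
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    mg_stop("output path is not writable", "mgmorph_bad_path")

  center <- shape / 2 * cal_spacing(cal)
  rows <- list()
  idx <- 0
  for (g in design$groups) {
    eff <- g$effects %||% list()
    p_g <- params
    if (!is.null(eff$soma_size))
      p_g$soma_semiaxes_um[1:2] <- p_g$soma_semiaxes_um[1:2] * sqrt(eff$soma_size)
    if (!is.null(eff$tree_length)) {
      p_g$primary_length_um <- p_g$primary_length_um * eff$tree_length
      p_g$child_length_um <- p_g$child_length_um * eff$tree_length
    }
    if (!is.null(eff$radius))
      p_g$radius_um <- p_g$radius_um * eff$radius
    for (m in seq_len(g$n_mice)) {
      mdir <- file.path(out_dir, paste0("group_", g$name), paste0("mouse_", m))
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      for (cidx in seq_len(cpm)) {
        idx <- idx + 1
        cs <- derive_seed(seed, idx)
        cell <- generate_cell(p_g, seed = cs, center_um = center)
        mask <- rasterize_cell(cell$spec, cal, shape)
        nm <- noise; nm$seed <- derive_seed(cs, 1L)
        stk <- render_stack(list(iba1 = mask), nm, cal)
        path <- file.path(mdir, sprintf("cell_%02d.tif", cidx))
        write_stack(stk, path)
        roi <- soma_roi_from_spec(cell$spec, cal,
                                  mouse = paste0(g$name, "_m", m),
                                  cell = sprintf("%s_m%d_c%02d", g$name, m, cidx))
        write_roi_json(roi, sub("\\.tif$", "_soma.json", path))
        rows[[idx]] <- cbind(data.frame(group = g$name, mouse = m, cell = cidx,
                                        seed = cs,
                                        path = sub(paste0("^", out_dir, "/?"),
                                                   "", path),
                                        stringsAsFactors = FALSE),
                             cell$truth)
      }
    }
  }
  truth <- do.call(rbind, rows)
  write_records(truth, file.path(out_dir, "truth_cells.csv"))
  metrics <- c("volume_um3", "surface_um2", "branch_count", "tree_length_um",
               "average_branch_length_um", "soma_area_um2", "com_offset_um")
  summ <- do.call(rbind, lapply(split(truth, truth$group), function(tg) {
    data.frame(group = tg$group[1], metric = metrics,
               mean = vapply(metrics, function(k) mean(tg[[k]]), numeric(1)),
               sd = vapply(metrics, function(k) sd(tg[[k]]), numeric(1)),
               sem = vapply(metrics, function(k) sd(tg[[k]]) / sqrt(nrow(tg)),
                            numeric(1)),
               n = nrow(tg), stringsAsFactors = FALSE)
  }))
  write_records(summ, file.path(out_dir, "truth_cohort.csv"))
  yaml::write_yaml(list(
    groups = lapply(design$groups, function(g)
      list(name = g$name, n_mice = g$n_mice, effects = g$effects %||% list())),
    cells_per_mouse = cpm, seed = seed,
    calibration = list(xy_um_per_px = cal$xy_um_per_px,
                       z_um_per_voxel = cal$z_um_per_voxel),
    shape = as.integer(shape),
    noise = unclass(noise)), file.path(out_dir, "design.yaml"))
  invisible(truth)
}

# mid-plane soma ellipse as a 64-gon ROI, in pixel coordinates
soma_roi_from_spec <- function(spec, cal, mouse = NA, cell = NA) {
  xy <- cal$xy_um_per_px
  c0 <- spec$soma_center_um
  ax <- spec$soma_semiaxes_um
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  # dim1 (rows) <-> y, dim2 (cols) <-> x
  soma_roi(cbind((c0[2] + ax[2] * sin(th)) / xy,
                 (c0[1] + ax[1] * cos(th)) / xy),
           cal = cal, mouse = mouse, cell = cell)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
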