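#' Rasterize a tube of constant radius around a space curve
#'
#' A voxel is foreground iff its world-coordinate center lies within
#' `radius_mm` of the (densely sampled) curve. Sampling must be dense
#' relative to the grid — step at most half the minimum spacing — so the
#' sampled polyline is indistinguishable from the continuous curve at voxel
#' resolution.
#'
#' Tube ends are flat by default (`caps = "flat"`): voxels whose projection
#' falls beyond the curve's end planes are clipped, so a straight tube is a
#' true cylinder and its voxel volume converges to `pi r^2 L` under grid
#' refinement. `caps = "round"` keeps the capsule (union-of-balls) shape.
#'
#' @param curve n x 3 matrix of points along the curve, in mm (world
#'   coordinates), sampled with step <= min(spacing)/2.
#' @param radius_mm tube radius in mm (> 0).
#' @param grid the target [grid_spec()].
#' @param caps `"flat"` (cylinder-like ends) or `"round"` (capsule).
#' @return a `vessel_mask` on `grid`.
#' @export
rasterize_tube <- function(curve, radius_mm, grid, caps = c("flat", "round")) {
  caps <- match.arg(caps)
  stopifnot(inherits(grid, "grid_spec"), radius_mm > 0)
  if (is.null(dim(curve))) curve <- matrix(curve, ncol = 3)
  d <- grid$shape
  vox <- world_to_voxel(grid, curve)
  out_lo <- vox < 1 - 1e-9
  out_hi <- sweep(vox, 2, d) > 1e-9
  if (any(out_lo | out_hi)) {
    bad <- which(apply(out_lo | out_hi, 1, any))[1]
    stop(sprintf(
      "curve exits grid at point %d: world (%.2f, %.2f, %.2f) mm",
      bad, curve[bad, 1], curve[bad, 2], curve[bad, 3]), call. = FALSE)
  }
  # per-axis half-widths of the candidate index box around each sample
  halfw <- ceiling(radius_mm / grid$spacing) + 1L
  arr <- array(FALSE, dim = d)
  r2 <- radius_mm^2
  for (s in seq_len(nrow(curve))) {
    c0 <- vox[s, ]
    lo <- pmax(1L, floor(c0 - halfw))
    hi <- pmin(d, ceiling(c0 + halfw))
    ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
    kk <- seq.int(lo[3], hi[3])
    box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    w <- voxel_to_world(grid, box)
    dd <- (w[, 1] - curve[s, 1])^2 + (w[, 2] - curve[s, 2])^2 +
          (w[, 3] - curve[s, 3])^2
    hit <- dd <= r2
    if (any(hit))
      arr[ijk_to_linear(box[hit, , drop = FALSE], d)] <- TRUE
  }
  n <- nrow(curve)
  open_curve <- max(abs(curve[n, ] - curve[1, ])) > 1e-9
  if (caps == "flat" && n >= 2L && open_curve) {
    fgl <- which(arr)
    if (length(fgl)) {
      w <- voxel_to_world(grid, linear_to_ijk(fgl, d))
      t0 <- curve[2, ] - curve[1, ]
      t0 <- t0 / sqrt(sum(t0^2))
      t1 <- curve[n, ] - curve[n - 1L, ]
      t1 <- t1 / sqrt(sum(t1^2))
      beyond <- (sweep(w, 2, curve[1, ]) %*% t0 < 0) |
                (sweep(w, 2, curve[n, ]) %*% t1 > 0)
      arr[fgl[beyond]] <- FALSE
    }
  }
  vessel_mask(arr * 1.0, grid)
}

sample_polyline <- function(points, step) {
  # resample a polyline at (at most) `step` spacing, keeping the vertices
  segs <- list(points[1, , drop = FALSE])
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n
    segs[[s + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2]),
                            a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, segs)
}

#' Default phantom grid
#'
#' An isotropic cube grid; the default 128^3 voxels at 0.5 mm keeps phantom
#' generation and feature extraction at seconds scale.
#'
#' @param n voxels per axis.
#' @param spacing isotropic spacing in mm.
#' @return a [grid_spec()].
#' @export
default_phantom_grid <- function(n = 128L, spacing = 0.5) {
  grid_spec(rep(n, 3), spacing = rep(spacing, 3))
}

#' Generate a synthetic vascular phantom with analytic ground truth
#'
#' Produces a binary mask plus a truth record of the morphology the generator
#' planted: bifurcation/endpoint counts, per-branch analytic length, chord
#' and tortuosity, and the tube radius. Kinds:
#'
#' * `straight_tube` — axis-diagonal straight cylinder; tortuosity 1.
#' * `arc_tube` — circular arc of radius `arc_radius_mm` spanning
#'   `arc_angle` radians; analytic tortuosity
#'   `(R * theta) / (2 R sin(theta/2))` (pi/2 for a semicircle).
#' * `helix_tube` — helix with given winding radius, pitch and turns.
#' * `y_tree` — one trunk splitting into two straight branches: 1
#'   bifurcation, 3 endpoints, 3 segments.
#' * `random_binary_tree` — seeded recursive binary branching with branch
#'   angles and lengths drawn uniformly from bounds, rejection-sampled so
#'   non-adjacent branches stay more than 4 radii apart and everything fits
#'   inside the grid with margin. The seed fully determines the tree.
#'
#' The expected total volume in the truth record is analytic
#' (`pi r^2 * total length`); for multi-branch phantoms the rasterized union
#' (what [total_volume()] measures) is smaller than the sum of branch
#' cylinders by the junction overlap, so the truth also carries a
#' `junction_overlap` flag.
#'
#' @param kind one of `"straight_tube"`, `"arc_tube"`, `"helix_tube"`,
#'   `"y_tree"`, `"random_binary_tree"`.
#' @param radius_mm tube radius in mm. For `random_binary_tree`, if `NULL`
#'   the radius is drawn uniformly from `radius_range_mm`.
#' @param grid target grid; defaults to 128^3 voxels at 0.5 mm isotropic,
#'   small enough for seconds-scale runs.
#' @param length_mm tube length (straight tube) in mm.
#' @param direction straight-tube axis (world space); axis-aligned by
#'   default so the digital centerline is collinear. Oblique directions give
#'   the zig-zag path-length inflation inherent to voxel centerlines.
#' @param arc_radius_mm,arc_angle arc geometry (arc tube).
#' @param helix_radius_mm,helix_pitch_mm,helix_turns helix geometry.
#' @param branch_length_mm trunk/branch length for `y_tree`.
#' @param branch_angle full opening half-angle for `y_tree` (radians).
#' @param n_bifurcations planned bifurcation count for `random_binary_tree`.
#' @param radius_range_mm,length_range_mm,angle_range random-tree draw bounds.
#' @param seed integer seed (random tree); same seed, same mask.
#' @return list with `mask` (a `vessel_mask`) and `truth` (list: counts,
#'   `radius_mm`, `branches` tibble with analytic `length_mm`, `chord_mm`,
#'   `tortuosity`, `volume_mm3` analytic, `junction_overlap` flag).
#' @export
make_phantom <- function(kind = c("straight_tube", "arc_tube", "helix_tube",
                                  "y_tree", "random_binary_tree"),
                         radius_mm = 2, grid = default_phantom_grid(),
                         length_mm = 40, direction = c(0, 0, 1),
                         arc_radius_mm = 20, arc_angle = pi,
                         helix_radius_mm = 12, helix_pitch_mm = 10,
                         helix_turns = 2,
                         branch_length_mm = 20, branch_angle = pi / 5,
                         n_bifurcations = 3,
                         radius_range_mm = c(1, 3),
                         length_range_mm = c(10, 18),
                         angle_range = c(pi / 7, pi / 3.6),
                         seed = 1L) {
  kind <- match.arg(kind)
  step <- min(grid$spacing) / 4
  # generic sub-voxel offset: curves commensurate with the lattice (axis
  # exactly on or exactly between voxel centers) are measure-zero in real
  # data but pathological for digital topology and for volume quantization
  center <- voxel_to_world(grid, matrix((grid$shape + 1) / 2, ncol = 3))[1, ] +
    grid$spacing * c(0.13, 0.37, 0.29)
  switch(kind,
    straight_tube = {
      # axis-aligned: the thinned centerline is collinear, tortuosity exactly 1
      u <- direction / sqrt(sum(direction^2))
      t <- seq(-length_mm / 2, length_mm / 2, by = step)
      curve <- cbind(center[1] + t * u[1], center[2] + t * u[2],
                     center[3] + t * u[3])
      mask <- rasterize_tube(curve, radius_mm, grid)
      truth <- phantom_truth(
        branches = tibble::tibble(length_mm = length_mm,
                                  chord_mm = length_mm, tortuosity = 1),
        n_bifurcations = 0L, n_endpoints = 2L, radius_mm = radius_mm,
        junction_overlap = FALSE)
      list(mask = mask, truth = truth)
    },
    arc_tube = {
      theta <- seq(0, arc_angle, by = step / arc_radius_mm)
      curve <- cbind(center[1] + arc_radius_mm * cos(theta),
                     center[2] + arc_radius_mm * sin(theta),
                     center[3] + 0 * theta)
      curve[, 1] <- curve[, 1] - arc_radius_mm * (1 + cos(arc_angle)) / 2
      curve[, 2] <- curve[, 2] - arc_radius_mm * sin(arc_angle) / 2
      len <- arc_radius_mm * arc_angle
      chord <- 2 * arc_radius_mm * sin(arc_angle / 2)
      mask <- rasterize_tube(curve, radius_mm, grid)
      truth <- phantom_truth(
        branches = tibble::tibble(length_mm = len, chord_mm = chord,
                                  tortuosity = len / chord),
        n_bifurcations = 0L, n_endpoints = 2L, radius_mm = radius_mm,
        junction_overlap = FALSE)
      list(mask = mask, truth = truth)
    },
    helix_tube = {
      total_angle <- 2 * pi * helix_turns
      dl <- sqrt(helix_radius_mm^2 + (helix_pitch_mm / (2 * pi))^2)
      theta <- seq(0, total_angle, by = step / dl)
      z0 <- helix_pitch_mm * helix_turns / 2
      curve <- cbind(center[1] + helix_radius_mm * cos(theta),
                     center[2] + helix_radius_mm * sin(theta),
                     center[3] - z0 + helix_pitch_mm * theta / (2 * pi))
      len <- total_angle * dl
      chord <- sqrt(sum((curve[nrow(curve), ] - curve[1, ])^2))
      mask <- rasterize_tube(curve, radius_mm, grid)
      truth <- phantom_truth(
        branches = tibble::tibble(length_mm = len, chord_mm = chord,
                                  tortuosity = len / chord),
        n_bifurcations = 0L, n_endpoints = 2L, radius_mm = radius_mm,
        junction_overlap = FALSE)
      list(mask = mask, truth = truth)
    },
    y_tree = {
      root <- center - c(0, 0, branch_length_mm)
      junc <- center
      u1 <- c(sin(branch_angle), 0, cos(branch_angle))
      u2 <- c(-sin(branch_angle), 0, cos(branch_angle))
      tips <- rbind(junc + branch_length_mm * u1,
                    junc + branch_length_mm * u2)
      branches <- list(rbind(root, junc),
                       rbind(junc, tips[1, ]), rbind(junc, tips[2, ]))
      mask <- rasterize_branches(branches, radius_mm, grid, step)
      truth <- phantom_truth(
        branches = tibble::tibble(length_mm = rep(branch_length_mm, 3),
                                  chord_mm = rep(branch_length_mm, 3),
                                  tortuosity = rep(1, 3)),
        n_bifurcations = 1L, n_endpoints = 3L, radius_mm = radius_mm,
        junction_overlap = TRUE)
      list(mask = mask, truth = truth)
    },
    random_binary_tree = {
      make_random_tree(grid, n_bifurcations, radius_mm, radius_range_mm,
                       length_range_mm, angle_range, seed, step)
    }
  )
}

phantom_truth <- function(branches, n_bifurcations, n_endpoints, radius_mm,
                          junction_overlap) {
  list(
    n_bifurcations = n_bifurcations,
    n_endpoints = n_endpoints,
    n_segments = nrow(branches),
    radius_mm = radius_mm,
    branches = branches,
    total_length_mm = sum(branches$length_mm),
    analytic_volume_mm3 = pi * radius_mm^2 * sum(branches$length_mm),
    junction_overlap = junction_overlap
  )
}

rasterize_branches <- function(branches, radius_mm, grid, step) {
  d <- grid$shape
  acc <- array(FALSE, dim = d)
  for (b in branches) {
    curve <- sample_polyline(b, step)
    m <- rasterize_tube(curve, radius_mm, grid)
    acc <- acc | (m$values > 0)
  }
  vessel_mask(acc * 1.0, grid)
}

# seeded recursive binary branching with separation constraints
make_random_tree <- function(grid, n_bifurcations, radius_mm,
                             radius_range_mm, length_range_mm, angle_range,
                             seed, step) {
  rng <- local_rng(seed)
  r <- if (is.null(radius_mm))
    stats::runif(1, radius_range_mm[1], radius_range_mm[2]) else radius_mm
  margin <- r + 2 * max(grid$spacing)
  lo <- voxel_to_world(grid, matrix(c(1, 1, 1), ncol = 3))[1, ] + margin
  hi <- voxel_to_world(grid, matrix(grid$shape, ncol = 3))[1, ] - margin
  bounds_ok <- function(p) all(p >= lo) && all(p <= hi)
  center <- (lo + hi) / 2
  sep <- 4 * r

  # segments: list of (a, b, parent_id); tips: ids of segments whose far end
  # can still branch
  root_dir <- rand_unit()
  root_len <- stats::runif(1, length_range_mm[1], length_range_mm[2])
  a0 <- center - root_dir * root_len / 2
  b0 <- a0 + root_dir * root_len
  tries <- 0L
  while ((!bounds_ok(a0) || !bounds_ok(b0)) && tries < 100L) {
    root_dir <- rand_unit()
    a0 <- center - root_dir * root_len / 2
    b0 <- a0 + root_dir * root_len
    tries <- tries + 1L
  }
  if (!bounds_ok(a0) || !bounds_ok(b0))
    stop("infeasible phantom: root segment cannot be placed inside the grid",
         call. = FALSE)
  segs <- list(list(a = a0, b = b0, parent = 0L))
  tips <- 1L
  planted_bifs <- 0L

  while (planted_bifs < n_bifurcations && length(tips) > 0L) {
    placed <- FALSE
    for (tip_pos in sample(seq_along(tips))) {
      tip <- tips[tip_pos]
      p <- segs[[tip]]$b
      dir0 <- segs[[tip]]$b - segs[[tip]]$a
      dir0 <- dir0 / sqrt(sum(dir0^2))
      for (attempt in seq_len(60L)) {
        ang1 <- stats::runif(1, angle_range[1], angle_range[2])
        ang2 <- stats::runif(1, angle_range[1], angle_range[2])
        az <- stats::runif(1, 0, 2 * pi)
        d1 <- rotate_about(dir0, ang1, az)
        d2 <- rotate_about(dir0, -ang2, az)
        if (sum(d1 * d2) > cos(pi / 4)) next # siblings too parallel
        l1 <- stats::runif(1, length_range_mm[1], length_range_mm[2])
        l2 <- stats::runif(1, length_range_mm[1], length_range_mm[2])
        c1 <- list(a = p, b = p + d1 * l1, parent = tip)
        c2 <- list(a = p, b = p + d2 * l2, parent = tip)
        if (!bounds_ok(c1$b) || !bounds_ok(c2$b)) next
        if (!separated(c1, segs, tip, sep) || !separated(c2, segs, tip, sep))
          next
        if (seg_seg_dist_far(c1, c2) <= sep) next
        segs <- c(segs, list(c1), list(c2))
        tips <- c(tips[-tip_pos], length(segs) - 1L, length(segs))
        planted_bifs <- planted_bifs + 1L
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) break # no tip can branch under the separation constraints
  }
  on.exit(rng(), add = TRUE)

  branches <- lapply(segs, function(s) rbind(s$a, s$b))
  mask <- rasterize_branches(branches, r, grid, step)
  lens <- vapply(segs, function(s) sqrt(sum((s$b - s$a)^2)), numeric(1))
  truth <- phantom_truth(
    branches = tibble::tibble(length_mm = lens, chord_mm = lens,
                              tortuosity = rep(1, length(lens))),
    n_bifurcations = planted_bifs,
    n_endpoints = planted_bifs + 2L,
    radius_mm = r,
    junction_overlap = planted_bifs > 0L)
  truth$seed <- seed
  list(mask = mask, truth = truth)
}

# minimum distance between candidate segment and all non-adjacent segments
separated <- function(cand, segs, parent, sep) {
  for (id in seq_along(segs)) {
    if (id == parent) next
    s <- segs[[id]]
    # skip segments sharing the junction point
    if (max(abs(s$b - cand$a)) < 1e-9 || max(abs(s$a - cand$a)) < 1e-9) next
    if (seg_seg_dist(cand$a, cand$b, s$a, s$b) <= sep) return(FALSE)
  }
  TRUE
}

# distance between the far halves of two sibling segments (shared origin)
seg_seg_dist_far <- function(s1, s2) {
  m1 <- (s1$a + s1$b) / 2
  m2 <- (s2$a + s2$b) / 2
  seg_seg_dist(m1, s1$b, m2, s2$b)
}

# minimum distance between 3D segments [p1,p2] and [q1,q2]
seg_seg_dist <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b * b
  if (den > 1e-12) {
    s <- clamp01((b * e - cc * d) / den)
  } else s <- 0
  t <- if (cc > 1e-12) clamp01((b * s + e) / cc) else 0
  s <- if (a > 1e-12) clamp01((b * t - d) / a) else 0
  dp <- w + s * u - t * v
  sqrt(sum(dp * dp))
}

clamp01 <- function(x) min(1, max(0, x))

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# rotate `dir` by `angle` away from itself, at azimuth `az` around it
rotate_about <- function(dir, angle, az) {
  # orthonormal frame around dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  axis <- cos(az) * e1 + sin(az) * e2
  cos(angle) * dir + sin(angle) * axis
}

# seed the RNG locally, restoring the caller's state on exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthesize a pseudo-anatomical volume paired to a mask
#'
#' Background intensity everywhere, vessel intensity inside the mask, plus
#' seeded additive Gaussian noise and an optional boxcar smoothing — a stand-in
#' (synthetic) for the paired anatomical contrasts used in segmentation
#' pipelines, sufficient to exercise resampling and thresholding plumbing.
#'
#' @param mask a `vessel_mask`.
#' @param vessel_intensity,background_intensity intensities (arbitrary units).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed; same seed, same volume.
#' @param smooth_voxels odd boxcar width in voxels (0 = none).
#' @return a [volume3d()] on the mask's grid.
#' @export
make_paired_anatomical <- function(mask, vessel_intensity = 200,
                                   background_intensity = 100,
                                   noise_sd = 0, seed = 1L,
                                   smooth_voxels = 0L) {
  stopifnot(inherits(mask, "vessel_mask"), noise_sd >= 0)
  vals <- background_intensity +
    (vessel_intensity - background_intensity) * mask$values
  if (smooth_voxels >= 3L) {
    k <- smooth_voxels %/% 2L
    sm <- vals
    for (ax in 1:3) {
      acc <- array(0, dim = dim(sm)); cnt <- 0L
      for (o in (-k):k) {
        acc <- acc + shift_array(sm, ax, o)
        cnt <- cnt + 1L
      }
      sm <- acc / cnt
    }
    vals <- sm
  }
  if (noise_sd > 0) {
    restore <- local_rng(seed)
    on.exit(restore(), add = TRUE)
    vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  }
  volume3d(array(vals, dim = dim(mask$values)), mask$grid)
}

# shift with edge replication along one axis
shift_array <- function(a, axis, off) {
  if (off == 0) return(a)
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
  args <- list(a, 1:d[1], 1:d[2], 1:d[3])
  args[[axis + 1L]] <- idx
  do.call(`[`, args)
}
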