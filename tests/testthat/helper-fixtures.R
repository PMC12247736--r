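# Fixture builders and independent oracles shared across the test files.
# All fixtures are generated in code; nothing is read from disk.

iso_grid <- function(n, s = 1) grid_spec(rep(n, 3), spacing = rep(s, 3))

mask_from_ijk <- function(ijk, grid) {
  a <- array(0, dim = grid$shape)
  a[ijk[, 1] + grid$shape[1] * (ijk[, 2] - 1) +
      grid$shape[1] * grid$shape[2] * (ijk[, 3] - 1)] <- 1
  vessel_mask(a, grid)
}

# straight 1-voxel-wide digital line along z
line_mask <- function(n_pts = 10, grid = iso_grid(20)) {
  c0 <- floor(grid$shape / 2)
  mask_from_ijk(cbind(c0[1], c0[2], seq_len(n_pts) + 3), grid)
}

# Y: three straight arms meeting at a single voxel
y_mask <- function(grid = iso_grid(24)) {
  c0 <- c(12L, 12L, 12L)
  arm1 <- cbind(12L, 12L, 4:12)                    # up the z axis
  arm2 <- cbind(12L + 1:7, 12L, 12L + 1:7)        # diagonal in xz
  arm3 <- cbind(12L - 1:7, 12L, 12L + 1:7)        # mirrored diagonal
  mask_from_ijk(rbind(arm1, arm2, arm3), grid)
}

# random blob: union of a few balls, reproducible
blob_mask <- function(seed, n = 24, n_balls = 4) {
  set.seed(seed)
  g <- iso_grid(n)
  a <- array(0, dim = g$shape)
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, min(4, n / 3), n - min(3, n / 3))
    r <- runif(1, 1.5, min(4, n / 3))
    hit <- rowSums(sweep(idx, 2, c0)^2) <= r^2
    a[idx[hit, , drop = FALSE]] <- 1
  }
  vessel_mask(a, g)
}

# independent component-count oracle built on igraph
count_components_oracle <- function(mask, connectivity = 26) {
  fg <- which(mask$values == 1, arr.ind = TRUE)
  n <- nrow(fg)
  if (n == 0) return(0L)
  edges <- integer(0)
  for (a in seq_len(n)) {
    d <- abs(sweep(fg, 2, fg[a, ]))
    if (connectivity == 26) {
      nb <- which(apply(d, 1, max) == 1)
    } else {
      nb <- which(rowSums(d) == 1)
    }
    nb <- nb[nb > a]
    if (length(nb)) edges <- c(edges, rbind(a, nb))
  }
  gph <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::count_components(gph)
}

# brute-force anisotropic EDT oracle: nearest background voxel center
edt_oracle <- function(mask, pts) {
  bg <- which(mask$values == 0, arr.ind = TRUE)
  sp <- mask$grid$spacing
  vapply(seq_len(nrow(pts)), function(r) {
    d2 <- (sp[1] * (bg[, 1] - pts[r, 1]))^2 +
          (sp[2] * (bg[, 2] - pts[r, 2]))^2 +
          (sp[3] * (bg[, 3] - pts[r, 3]))^2
    sqrt(min(d2))
  }, numeric(1))
}

# which skeleton voxels have no skeleton neighbors at all
.count_isolated <- function(sk) {
  g <- attr(sk, "grid")
  a <- array(FALSE, dim = g$shape)
  a[cbind(sk$i, sk$j, sk$k)] <- TRUE
  cnt <- vesselmorph:::.cpp_neighbor_count26(a, dim(a))
  cnt[cbind(sk$i, sk$j, sk$k)] == 0
}

# full pipeline shortcut
pipeline_tree <- function(mask) {
  decompose_skeleton(
    skeleton_radii(classify_skeleton(skeletonize(mask)), mask))
}
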