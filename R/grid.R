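#' Define a voxel grid
#'
#' A grid specification ties a voxel lattice to physical space: the number of
#' voxels per axis, the voxel spacing in mm, and a 4x4 affine mapping 0-based
#' voxel indices to world coordinates in mm. All lengths, radii and volumes
#' reported by this package are physical (mm), never voxel counts, so every
#' measurement flows through a `grid_spec`.
#'
#' @param shape integer vector of length 3; voxels per axis.
#' @param spacing numeric vector of length 3; mm per voxel per axis. Ignored
#'   when `affine` is given (it is then derived from the affine column norms).
#' @param affine optional 4x4 matrix mapping homogeneous 0-based voxel indices
#'   to mm. Defaults to `diag(spacing)` with zero origin.
#' @return an object of class `grid_spec` with fields `shape`, `spacing`,
#'   `affine`.
#' @export
#' @examples
#' g <- grid_spec(c(64, 64, 32), spacing = c(0.47, 0.47, 0.8))
#' voxel_volume(g)
grid_spec <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be 3 strictly positive reals", call. = FALSE)
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("`affine` must be a 4x4 matrix", call. = FALSE)
    if (abs(det(affine)) < .Machine$double.eps * 64)
      stop("`affine` is singular (non-invertible grid-to-world transform)",
           call. = FALSE)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0))
      stop("`affine` has a zero-length column; spacing must be positive",
           call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = spacing, affine = affine),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `voxel_volume()`: the physical volume of one voxel in mm^3
#'   (absolute determinant of the affine's linear part).
#' @export
voxel_volume <- function(grid) {
  abs(det(grid$affine[1:3, 1:3]))
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based (R array convention) in the interface; the affine
#' acts on 0-based indices, so the conversion subtracts 1 internally.
#'
#' @param grid a `grid_spec`.
#' @param ijk numeric matrix (n x 3) of 1-based voxel indices (may be
#'   fractional).
#' @return `voxel_to_world()`: n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind2matrix(ijk)
  h <- cbind(ijk - 1, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz numeric matrix (n x 3) of world coordinates in mm.
#' @return `world_to_voxel()`: n x 3 matrix of (possibly fractional) 1-based
#'   voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind2matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE] + 1
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) <= tol
}

rbind2matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = ncol(x))
}
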