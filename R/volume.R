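#' Volumes and binary vessel masks
#'
#' A `volume3d` is a 3D scalar array tied to a [grid_spec()]; a
#' `vessel_mask` is a `volume3d` whose values are exactly 0 or 1, the
#' representation of a binary vascular segmentation.
#'
#' @param values 3D numeric array.
#' @param grid a [grid_spec()] whose shape matches `dim(values)`.
#' @return a `volume3d` (list with `values`, `grid`).
#' @export
volume3d <- function(values, grid) {
  if (length(dim(values)) != 3L)
    stop("not a 3D volume: `values` must have exactly 3 dimensions",
         call. = FALSE)
  if (!all(dim(values) == grid$shape))
    stop("`values` dimensions do not match grid shape", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  structure(list(values = values, grid = grid), class = "volume3d")
}

#' @rdname volume3d
#' @export
vessel_mask <- function(values, grid) {
  values <- values * 1.0
  if (!all(values == 0 | values == 1))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  v <- volume3d(values, grid)
  class(v) <- c("vessel_mask", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (inherits(x, "vessel_mask")) "vessel_mask" else "volume3d"
  cat("<", kind, "> ", paste(x$grid$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$grid$spacing, 4), collapse = " x "),
      " mm", sep = "")
  if (kind == "vessel_mask")
    cat(", ", sum(x$values), " foreground voxels", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 image and returns it with the spacing and
#' grid-to-world affine taken from the header (sform/qform). No resampling or
#' reorientation is performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume3d()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  # tolerate trailing singleton dims (e.g. 3D stored as X x Y x Z x 1)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("not a 3D volume: image has ", length(d), " dimensions",
         call. = FALSE)
  if (!all(is.finite(arr)))
    stop("volume contains non-finite values", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  storage.mode(arr) <- "double"
  attributes(arr) <- list(dim = d)
  volume3d(arr, grid_spec(d, affine = aff))
}

#' Write a NIfTI volume
#'
#' Writes values as float64 so that a round trip through [load_volume()]
#' reproduces them bit-exactly; the affine is stored as sform (and qform),
#' preserved to better than 1e-6 mm.
#'
#' @param vol a [volume3d()] or `vessel_mask`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist
#'   and be writable.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("cannot write to directory: ", dir, call. = FALSE)
  arr <- vol$values
  attr(arr, "pixdim") <- vol$grid$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  m <- structure(vol$grid$affine, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume onto a target grid by trilinear interpolation
#'
#' Each output voxel takes the trilinear interpolation of the source volume
#' at the output voxel's world coordinate; world coordinates outside the
#' source domain are filled with 0 (background), the appropriate fill for
#' masks and brain-extracted anatomicals.
#'
#' @param vol a [volume3d()].
#' @param target a [grid_spec()] for the output.
#' @return a [volume3d()] on `target`.
#' @export
resample_trilinear <- function(vol, target) {
  stopifnot(inherits(vol, "volume3d"), inherits(target, "grid_spec"))
  if (same_grid(vol$grid, target, tol = 0)) {
    out <- vol$values
    return(volume3d(out, target))
  }
  src <- vol$values
  sd <- dim(src)
  nx <- target$shape[1]; ny <- target$shape[2]; nz <- target$shape[3]
  out <- array(0, dim = c(nx, ny, nz))
  # world coords of one output slice, mapped into fractional source indices;
  # slab-wise to bound memory
  xy <- cbind(rep(seq_len(nx), times = ny), rep(seq_len(ny), each = nx))
  A <- solve(vol$grid$affine) %*% target$affine # target voxel -> source voxel (0-based)
  for (z in seq_len(nz)) {
    h <- cbind(xy[, 1] - 1, xy[, 2] - 1, z - 1, 1) %*% t(A)
    p <- h[, 1:3, drop = FALSE] + 1 # fractional 1-based source indices
    i0 <- floor(p)
    f <- p - i0
    vals <- numeric(nrow(p))
    # gather the 8 corners; corners outside the source array contribute 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
      w <- (if (cx) f[, 1] else 1 - f[, 1]) *
           (if (cy) f[, 2] else 1 - f[, 2]) *
           (if (cz) f[, 3] else 1 - f[, 3])
      ok <- ii >= 1 & ii <= sd[1] & jj >= 1 & jj <= sd[2] & kk >= 1 & kk <= sd[3] & w > 0
      if (any(ok)) {
        lin <- ii[ok] + sd[1] * (jj[ok] - 1) + sd[1] * sd[2] * (kk[ok] - 1)
        vals[ok] <- vals[ok] + w[ok] * src[lin]
      }
    }
    out[, , z] <- vals
  }
  volume3d(out, target)
}

#' Threshold a volume into a binary vessel mask
#'
#' @param vol a [volume3d()].
#' @param threshold finite scalar; output is 1 where `vol > threshold`.
#'   Resampled masks are conventionally re-binarized at 0.5.
#' @return a `vessel_mask` on the same grid.
#' @export
binarize <- function(vol, threshold = 0.5) {
  stopifnot(inherits(vol, "volume3d"), is.finite(threshold))
  vessel_mask((vol$values > threshold) * 1.0, vol$grid)
}
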