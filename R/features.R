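#' Total vascular volume of a mask
#'
#' Foreground voxel count times the physical voxel volume (|det| of the
#' affine's linear part), in mm^3.
#'
#' @param mask a `vessel_mask`.
#' @return volume in mm^3.
#' @export
total_volume <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  sum(mask$values) * voxel_volume(mask$grid)
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, the standard segmentation-agreement
#' score in `[0, 1]`; defined as 1 when both masks are empty.
#'
#' @param a,b `vessel_mask`s on the same grid.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "vessel_mask"), inherits(b, "vessel_mask"))
  if (!same_grid(a$grid, b$grid))
    stop("masks are on different grids", call. = FALSE)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1.0)
  2 * sum(a$values * b$values) / (na + nb)
}

#' Names of the per-subject vessel features
#'
#' The 11-dimensional morphological summary: total volume, total centerline
#' length, counts of segments / bifurcations / endpoints, radius summaries
#' (mean, SD, max), tortuosity summaries (mean, SD), and mean segment length.
#' The set is configurable in [extract_features()]; this default covers every
#' quantity the extraction pipeline measures plus dispersion summaries.
#'
#' @return character vector of 11 feature names.
#' @export
vessel_feature_names <- function() {
  c("total_volume_mm3", "total_length_mm", "n_segments", "n_bifurcations",
    "n_endpoints", "mean_radius_mm", "sd_radius_mm", "max_radius_mm",
    "mean_tortuosity", "sd_tortuosity", "mean_segment_length_mm")
}

#' Extract the morphological feature vector from a vessel mask
#'
#' Runs the full quantification pipeline — thinning, topological
#' classification, distance-transform radii, segment decomposition and
#' per-segment geometry — and aggregates it into one feature row per subject.
#' Radii at bifurcation-node voxels are included in the radius summaries;
#' segments with undefined tortuosity (closed loops, single voxels) are
#' excluded from the tortuosity summaries; zero-length single-voxel segments
#' are excluded from the mean segment length. An empty mask yields zero
#' counts and volumes and `NA` (undefined) means — never an error.
#'
#' @param mask a `vessel_mask`.
#' @param features which feature columns to return; defaults to the full
#'   11-feature set of [vessel_feature_names()].
#' @param subject_id optional identifier prepended as a column.
#' @return a one-row tibble.
#' @export
extract_features <- function(mask, features = vessel_feature_names(),
                             subject_id = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  skel <- skeleton_radii(classify_skeleton(skeletonize(mask)), mask)
  tree <- decompose_skeleton(skel)
  segs <- tree$segments
  tort <- segs$tortuosity[!is.na(segs$tortuosity)]
  seg_len <- segs$length_mm[segs$length_mm > 0]
  out <- tibble::tibble(
    total_volume_mm3 = total_volume(mask),
    total_length_mm = sum(segs$length_mm),
    n_segments = nrow(segs),
    n_bifurcations = tree$n_bifurcations,
    n_endpoints = tree$n_endpoints,
    mean_radius_mm = mean_or_na(skel$radius_mm),
    sd_radius_mm = if (nrow(skel) > 1) stats::sd(skel$radius_mm) else NA_real_,
    max_radius_mm = if (nrow(skel) > 0) max(skel$radius_mm) else NA_real_,
    mean_tortuosity = mean_or_na(tort),
    sd_tortuosity = if (length(tort) > 1) stats::sd(tort) else NA_real_,
    mean_segment_length_mm = mean_or_na(seg_len)
  )
  out <- out[, features, drop = FALSE]
  if (!is.null(subject_id))
    out <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id), out)
  out
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Write a feature table with its configuration sidecar
#'
#' One CSV row per subject plus a JSON sidecar recording the feature-set
#' configuration and package version, so downstream model fits are traceable
#' to the extraction settings.
#'
#' @param features tibble of feature rows (e.g. bound [extract_features()]
#'   outputs).
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  sidecar <- list(
    feature_set = setdiff(names(features), "subject_id"),
    package = "vesselmorph",
    version = as.character(utils::packageVersion("vesselmorph"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
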