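#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)` by voxel count on a shared grid.
#'
#' @param a,b `binary_mask` objects on compatible geometries; at least one
#'   must be non-empty.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_compatible(a$geometry, b$geometry)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0 && nb == 0)
    abort_segvar("dice undefined: both masks empty", "segvar_error_undefined_metric")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Jaccard index between two masks
#'
#' `|A n B| / |A u B|` by voxel count.
#'
#' @inheritParams dice
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_compatible(a$geometry, b$geometry)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0 && nb == 0)
    abort_segvar("jaccard undefined: both masks empty", "segvar_error_undefined_metric")
  inter <- sum(a$voxels & b$voxels)
  inter / (na + nb - inter)
}

# Directed boundary distances in mm between two boundary voxel sets lying in
# a common cropped window: Euclidean distance map of each boundary honoring
# anisotropic spacing, sampled at the other boundary's voxel centres.
boundary_distances <- function(bva, bvb, spacing) {
  dims <- as.integer(dim(bva))
  da <- .edt_mm(as.logical(bva), dims, as.numeric(spacing))
  db <- .edt_mm(as.logical(bvb), dims, as.numeric(spacing))
  list(a_to_b = db[bva], b_to_a = da[bvb])
}

# Shared set-up for the two surface-distance metrics: boundary extraction on
# the full grid (so the array-border rule applies), then cropping both
# boundaries to their joint bounding box, which leaves point-to-set
# distances unchanged.
surface_distance_sets <- function(a, b) {
  check_compatible(a$geometry, b$geometry)
  if (!any(a$voxels) || !any(b$voxels))
    abort_segvar("surface distances undefined: empty mask",
                 "segvar_error_undefined_metric")
  ba <- boundary_extract(a)$voxels
  bb <- boundary_extract(b)$voxels
  bb_box <- bbox_union(mask_bbox(ba, 0L), mask_bbox(bb, 0L))
  boundary_distances(crop_voxels(ba, bb_box), crop_voxels(bb, bb_box),
                     a$geometry$spacing)
}

#' Hausdorff distance between two masks (mm)
#'
#' The exact symmetric (100th percentile) Hausdorff distance between the two
#' boundary voxel-centre point sets, honoring anisotropic spacing:
#' `max(max_p d(p, S_B), max_q d(q, S_A))`.
#'
#' @param a,b non-empty `binary_mask` objects on compatible geometries.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(a, b) {
  d <- surface_distance_sets(a, b)
  max(max(d$a_to_b), max(d$b_to_a))
}

#' Mean distance to agreement between two masks (mm)
#'
#' Average of the two directed mean boundary distances:
#' `(mean_p d(p, S_B) + mean_q d(q, S_A)) / 2` — the average symmetric
#' surface distance. With `pooled = TRUE` the alternative pooled-surface
#' mean `sum of all distances / total boundary count` is returned instead.
#'
#' @inheritParams hausdorff_distance
#' @param pooled use the pooled-surface variant instead of the mean of
#'   directed means.
#' @return distance in mm.
#' @export
mean_distance_to_agreement <- function(a, b, pooled = FALSE) {
  d <- surface_distance_sets(a, b)
  if (pooled)
    return(sum(d$a_to_b, d$b_to_a) / (length(d$a_to_b) + length(d$b_to_a)))
  (mean(d$a_to_b) + mean(d$b_to_a)) / 2
}

#' All four agreement metrics plus volumes for one mask pair
#'
#' Computes DSC, Jaccard, Hausdorff distance and mean distance to agreement
#' in one pass (the two surface metrics share their distance maps), plus
#' both volumes. Convention when exactly one mask is empty: the overlap
#' metrics are 0 (defined), the distance metrics are `NA` (undefined, to be
#' excluded from aggregation). Both masks empty is an error.
#'
#' @inheritParams dice
#' @return an object of class `similarity_result`: a list with fields
#'   `dsc`, `jaccard`, `hd_mm`, `mda_mm`, `vol_a_ml`, `vol_b_ml`.
#' @export
compare_masks <- function(a, b) {
  check_compatible(a$geometry, b$geometry)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0 && nb == 0)
    abort_segvar("similarity undefined: both masks empty",
                 "segvar_error_undefined_metric")
  inter <- sum(a$voxels & b$voxels)
  dsc <- 2 * inter / (na + nb)
  jac <- inter / (na + nb - inter)
  if (na == 0 || nb == 0) {
    hd <- NA_real_; mda <- NA_real_
  } else {
    d <- surface_distance_sets(a, b)
    hd <- max(max(d$a_to_b), max(d$b_to_a))
    mda <- (mean(d$a_to_b) + mean(d$b_to_a)) / 2
  }
  structure(list(dsc = dsc, jaccard = jac, hd_mm = hd, mda_mm = mda,
                 vol_a_ml = mask_volume_ml(a), vol_b_ml = mask_volume_ml(b)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> DSC %.3f, Jaccard %.3f, HD %s mm, MDA %s mm (%.2f / %.2f mL)\n",
    x$dsc, x$jaccard,
    ifelse(is.na(x$hd_mm), "NA", sprintf("%.2f", x$hd_mm)),
    ifelse(is.na(x$mda_mm), "NA", sprintf("%.2f", x$mda_mm)),
    x$vol_a_ml, x$vol_b_ml))
  invisible(x)
}

#' @export
as.data.frame.similarity_result <- function(x, ...) {
  data.frame(dsc = x$dsc, jaccard = x$jaccard, hd_mm = x$hd_mm,
             mda_mm = x$mda_mm, vol_a_ml = x$vol_a_ml, vol_b_ml = x$vol_b_ml)
}
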