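#' Geometry-aware binary mask
#'
#' A 3D logical voxel array tied to an [image_geometry()]. Empty masks are
#' valid; all structure delineations in the package are represented this way.
#'
#' @param voxels logical 3D array (or something coercible) with dimensions
#'   equal to `geometry$shape`.
#' @param geometry an `image_geometry`.
#' @return An object of class `binary_mask` with fields `voxels`, `geometry`.
#' @export
binary_mask <- function(voxels, geometry) {
  if (!inherits(geometry, "image_geometry"))
    abort_segvar("geometry must be an image_geometry", "segvar_error_geometry")
  v <- array(as.logical(voxels), dim = dim(voxels))
  if (is.null(dim(v)) || length(dim(v)) != 3L)
    abort_segvar("voxels must be a 3D array", "segvar_error_not_3d")
  if (!identical(as.integer(dim(v)), geometry$shape))
    abort_segvar("voxel array extent does not match geometry shape",
                 "segvar_error_geometry")
  if (anyNA(v))
    abort_segvar("mask voxels must not contain NA", "segvar_error_geometry")
  structure(list(voxels = v, geometry = geometry), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels set on %s grid (%.3f mL)\n",
              sum(x$voxels), paste(x$geometry$shape, collapse = "x"),
              mask_volume_ml(x)))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$voxels)

is_empty_mask <- function(mask) !any(mask$voxels)

#' Physical volume of a mask in millilitres
#'
#' `count(voxels) * spacing_x * spacing_y * spacing_z / 1000`.
#'
#' @param mask a `binary_mask`.
#' @return volume in mL.
#' @examples
#' g <- image_geometry(c(10, 10, 10), c(1, 1, 1))
#' m <- binary_mask(array(TRUE, c(10, 10, 10)), g)
#' mask_volume_ml(m) # 1 mL
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Extract the boundary voxels of a mask
#'
#' A set voxel is boundary if at least one of its six face-adjacent
#' neighbours is outside the mask; set voxels on the array border count as
#' boundary. Returns a mask of the same geometry.
#'
#' @param mask a `binary_mask`.
#' @return a `binary_mask` whose voxels are the boundary of `mask`.
#' @export
boundary_extract <- function(mask) {
  v <- mask$voxels
  if (!any(v)) return(binary_mask(v, mask$geometry))
  d <- dim(v)
  interior <- array(TRUE, d)
  # a voxel is interior only if all 6 face neighbours are set; border
  # voxels can never be interior
  shift_and <- function(acc, axis, dir) {
    nb <- array(FALSE, d)
    if (axis == 1L) {
      if (dir > 0) nb[-d[1], , ] <- v[-1, , ] else nb[-1, , ] <- v[-d[1], , ]
    } else if (axis == 2L) {
      if (dir > 0) nb[, -d[2], ] <- v[, -1, ] else nb[, -1, ] <- v[, -d[2], ]
    } else {
      if (dir > 0) nb[, , -d[3]] <- v[, , -1] else nb[, , -1] <- v[, , -d[3]]
    }
    acc & nb
  }
  for (axis in 1:3) for (dir in c(-1L, 1L)) interior <- shift_and(interior, axis, dir)
  binary_mask(v & !interior, mask$geometry)
}

#' Voxelwise union of masks
#'
#' @param masks a non-empty list of `binary_mask` objects on compatible
#'   geometries (or several masks given as separate arguments).
#' @return a `binary_mask`, the logical OR.
#' @export
union_masks <- function(masks) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  if (!is.list(masks) || length(masks) == 0)
    abort_segvar("union_masks needs a non-empty list of masks",
                 "segvar_error_empty_input")
  g <- masks[[1]]$geometry
  acc <- masks[[1]]$voxels
  for (m in masks[-1]) {
    check_compatible(g, m$geometry)
    acc <- acc | m$voxels
  }
  binary_mask(acc, g)
}

# Index bounding box of set voxels, expanded by `margin` voxels and clipped
# to the array; NULL for an empty mask.
mask_bbox <- function(voxels, margin = 1L) {
  idx <- which(voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  d <- dim(voxels)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_voxels <- function(voxels, bb) {
  voxels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

bbox_union <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(lo = pmin(a$lo, b$lo), hi = pmax(a$hi, b$hi))
}
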