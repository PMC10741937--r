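#' Image geometry of a voxel grid
#'
#' Describes the sampling grid every mask lives on: voxel counts per axis,
#' physical voxel spacing in millimetres, and the world position (mm) of the
#' centre of voxel (1,1,1). All masks of a case must share one compatible
#' geometry; the package never resamples.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#' @param origin numeric vector of length 3, world mm of the first voxel
#'   centre. Defaults to (0, 0, 0).
#' @return An object of class `image_geometry`.
#' @examples
#' g <- image_geometry(c(96, 96, 24), c(0.5, 0.5, 3.0))
#' @export
image_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3 || length(spacing) != 3 || length(origin) != 3)
    abort_segvar("shape, spacing and origin must each have length 3",
                 "segvar_error_geometry")
  if (any(shape < 1L))
    abort_segvar("all shape entries must be >= 1", "segvar_error_geometry")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort_segvar("all spacing entries must be finite and > 0",
                 "segvar_error_geometry")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_geometry")
}

#' Test whether two geometries are compatible
#'
#' Compatible means equal shape, equal spacing, and origins that differ by
#' less than `tol` mm on every axis.
#'
#' @param a,b `image_geometry` objects.
#' @param tol origin tolerance in mm.
#' @return `TRUE` or `FALSE`.
#' @export
geometry_compatible <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < tol)
}

check_compatible <- function(a, b) {
  if (!geometry_compatible(a, b))
    abort_segvar(
      sprintf("incompatible geometries: shape %s vs %s, spacing %s vs %s",
              paste(a$shape, collapse = "x"), paste(b$shape, collapse = "x"),
              paste(signif(a$spacing, 4), collapse = "x"),
              paste(signif(b$spacing, 4), collapse = "x")),
      "segvar_error_geometry")
  invisible(TRUE)
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param geometry an `image_geometry`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)
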