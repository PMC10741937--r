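#' Read a binary mask from a NIfTI volume
#'
#' Voxels are binarized as `value != 0`. Spacing is taken from the NIfTI
#' pixdim, the origin from the xform translation. If `expected_geometry` is
#' supplied the file's geometry must be compatible (equal shape/spacing,
#' origins within 1e-6 mm).
#'
#' @param path path to a 3D `.nii` / `.nii.gz` file.
#' @param expected_geometry optional `image_geometry` to verify against.
#' @return a `binary_mask`.
#' @export
load_mask_volume <- function(path, expected_geometry = NULL) {
  if (!file.exists(path))
    abort_segvar(sprintf("mask file not found: %s", path),
                 "segvar_error_missing_file")
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    abort_segvar(sprintf("expected a 3D volume, got %dD: %s", length(dm), path),
                 "segvar_error_not_3d")
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  geom <- image_geometry(dm, spacing, origin)
  if (!is.null(expected_geometry) && !geometry_compatible(expected_geometry, geom))
    abort_segvar(sprintf("geometry mismatch for %s: expected %s @ %s, found %s @ %s",
                         path,
                         paste(expected_geometry$shape, collapse = "x"),
                         paste(signif(expected_geometry$spacing, 6), collapse = "x"),
                         paste(geom$shape, collapse = "x"),
                         paste(signif(geom$spacing, 6), collapse = "x")),
                 "segvar_error_geometry")
  binary_mask(array(as.array(img) != 0, dim = dm), geom)
}

#' Write a binary mask as a NIfTI volume
#'
#' Round-trips exactly: `load_mask_volume(save_mask_volume(m, p))` restores
#' voxels bit-exactly and spacing/origin to better than 1e-6 mm.
#'
#' @param mask a `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_mask_volume <- function(mask, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    abort_segvar(sprintf("cannot write to %s", dir), "segvar_error_unwritable")
  g <- mask$geometry
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = g$shape))
  RNifti::pixdim(img) <- g$spacing
  m <- diag(c(g$spacing, 1))
  m[1:3, 4] <- g$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a case metadata table
#'
#' CSV with header `case_id,age,pirads,psa,isup`; PI-RADS must be in
#' \{3, 4, 5\}, PSA positive, ISUP in 1..5.
#'
#' @param path CSV path.
#' @return a data.frame with one row per case.
#' @export
load_case_meta <- function(path) {
  if (!file.exists(path))
    abort_segvar(sprintf("metadata file not found: %s", path),
                 "segvar_error_missing_file")
  meta <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "age", "pirads", "psa", "isup")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    abort_segvar(sprintf("metadata is missing columns: %s",
                         paste(missing, collapse = ", ")),
                 "segvar_error_metadata")
  validate_case_meta(meta)
  meta
}

validate_case_meta <- function(meta) {
  if (!all(meta$pirads %in% c(3L, 4L, 5L)))
    abort_segvar("pirads values must be in {3,4,5}", "segvar_error_metadata")
  if (any(meta$psa <= 0))
    abort_segvar("psa values must be > 0", "segvar_error_metadata")
  if (!all(meta$isup %in% 1:5))
    abort_segvar("isup values must be in 1..5", "segvar_error_metadata")
  if (anyDuplicated(meta$case_id))
    abort_segvar("duplicate case_id in metadata", "segvar_error_metadata")
  invisible(meta)
}

# Directory layout helpers: {case_id}/{reader_id}/{structure}_{sequence}.nii.gz
# Gland structures carry no sequence suffix; derived unions append "_union"
# with the component labels joined by "_" (so the post-hoc union "T2+ADC"
# becomes dil_T2_ADC_union.nii.gz, distinct from the jointly-read T2ADC).
mask_filename <- function(structure, sequence = NA_character_) {
  if (is.na(sequence)) return(sprintf("%s.nii.gz", structure))
  if (sequence %in% union_sequence_labels()) {
    comp <- strsplit(sequence, "+", fixed = TRUE)[[1]]
    return(sprintf("%s_%s_union.nii.gz", structure, paste(comp, collapse = "_")))
  }
  sprintf("%s_%s.nii.gz", structure, sequence)
}

mask_path <- function(root, case_id, reader_id, structure, sequence = NA_character_) {
  file.path(root, case_id, reader_id, mask_filename(structure, sequence))
}
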