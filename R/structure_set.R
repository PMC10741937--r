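#' Sequence labels
#'
#' The eight delineated lesion sets (single sequences and jointly-displayed
#' combinations read as one image) and the four derived post-hoc unions.
#' `"T2ADC"` (jointly delineated) and `"T2+ADC"` (voxelwise union of the T2
#' and ADC delineations) are distinct labels throughout and must never be
#' conflated.
#'
#' @return character vector of labels.
#' @export
delineated_sequence_labels <- function() {
  c("T2", "ADC", "T2ADC", "B2000", "T2ADCB2000", "DCE", "T2ADCDCE", "ALL")
}

#' @rdname delineated_sequence_labels
#' @export
union_sequence_labels <- function() {
  c("T2+ADC", "T2+ADC+B2000", "T2+ADC+DCE", "T2+ADC+B2000+DCE")
}

#' @rdname delineated_sequence_labels
#' @export
all_sequence_labels <- function() {
  c(delineated_sequence_labels(), union_sequence_labels())
}

union_components <- function(label) {
  strsplit(label, "+", fixed = TRUE)[[1]]
}

gland_structures <- function() c("prostate", "tz", "pz")

#' One reader's delineations for one case
#'
#' Bundles the gland structures (prostate, transition zone, peripheral zone)
#' and the per-sequence dominant-index-lesion masks of a single reader, all
#' on one compatible grid.
#'
#' @param case_id,reader_id identifiers.
#' @param prostate,tz,pz `binary_mask` objects for the gland structures.
#' @param dil named list of `binary_mask`, names from
#'   [all_sequence_labels()] (union labels may be absent until
#'   [build_union_sets()] has run).
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(case_id, reader_id, prostate, tz, pz, dil) {
  g <- prostate$geometry
  for (m in c(list(tz, pz), dil)) check_compatible(g, m$geometry)
  bad <- setdiff(names(dil), all_sequence_labels())
  if (length(bad))
    abort_segvar(sprintf("unknown sequence labels: %s", paste(bad, collapse = ", ")),
                 "segvar_error_sequence_label")
  structure(list(case_id = case_id, reader_id = reader_id,
                 prostate = prostate, tz = tz, pz = pz, dil = dil),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> case %s, reader %s: %d lesion sets on %s grid\n",
              x$case_id, x$reader_id, length(x$dil),
              paste(x$prostate$geometry$shape, collapse = "x")))
  invisible(x)
}

#' Add the four derived union lesion sets to a structure set
#'
#' From the single-sequence delineations builds: T2+ADC, T2+ADC+B2000,
#' T2+ADC+DCE and T2+ADC+B2000+DCE as voxelwise unions.
#'
#' @param s a `structure_set` containing the T2, ADC, B2000 and DCE masks.
#' @return `s` with the four union labels added to `s$dil`.
#' @export
build_union_sets <- function(s) {
  need <- c("T2", "ADC", "B2000", "DCE")
  missing <- setdiff(need, names(s$dil))
  if (length(missing))
    abort_segvar(sprintf("cannot build union sets, missing component masks: %s",
                         paste(missing, collapse = ", ")),
                 "segvar_error_missing_component")
  for (lab in union_sequence_labels())
    s$dil[[lab]] <- union_masks(s$dil[union_components(lab)])
  s
}

#' Write a structure set into the on-disk cohort layout
#'
#' @param s a `structure_set`.
#' @param root cohort root directory.
#' @return invisibly, the vector of files written.
#' @export
save_structure_set <- function(s, root) {
  written <- character(0)
  for (st in gland_structures()) {
    p <- mask_path(root, s$case_id, s$reader_id, st)
    save_mask_volume(s[[st]], p)
    written <- c(written, p)
  }
  for (lab in names(s$dil)) {
    p <- mask_path(root, s$case_id, s$reader_id, "dil", lab)
    save_mask_volume(s$dil[[lab]], p)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read one reader's structure set from the on-disk cohort layout
#'
#' @param root cohort root directory.
#' @param case_id,reader_id identifiers.
#' @param expected_geometry optional geometry every mask must match.
#' @return a `structure_set`; union labels are loaded when present.
#' @export
load_structure_set <- function(root, case_id, reader_id,
                               expected_geometry = NULL) {
  get_mask <- function(structure, sequence = NA_character_, required = TRUE) {
    p <- mask_path(root, case_id, reader_id, structure, sequence)
    if (!file.exists(p)) {
      if (required)
        abort_segvar(sprintf("missing mask file: %s", p),
                     "segvar_error_missing_file")
      return(NULL)
    }
    load_mask_volume(p, expected_geometry)
  }
  prostate <- get_mask("prostate")
  dil <- list()
  for (lab in delineated_sequence_labels())
    dil[[lab]] <- get_mask("dil", lab)
  for (lab in union_sequence_labels()) {
    m <- get_mask("dil", lab, required = FALSE)
    if (!is.null(m)) dil[[lab]] <- m
  }
  structure_set(case_id, reader_id,
                prostate = prostate, tz = get_mask("tz"), pz = get_mask("pz"),
                dil = dil)
}
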