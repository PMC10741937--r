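#' Pairwise reader comparisons across a cohort
#'
#' For every case with all readers present, computes the four agreement
#' metrics for each unordered reader pair, for the three gland structures
#' and every lesion sequence label shared by all readers of that case. Cases
#' missing a reader are skipped with a warning, never silently dropped.
#' Undefined distance metrics (one empty mask) are carried as `NA`; pairs
#' with both masks empty have all metrics `NA`.
#'
#' @param cohort list of `structure_set` objects (any order; grouped by
#'   `case_id`).
#' @param n_readers expected readers per case (default 3).
#' @return data.frame with columns `case_id, reader_a, reader_b, structure,
#'   sequence, dsc, jaccard, hd_mm, mda_mm, vol_a_ml, vol_b_ml`; gland rows
#'   have `sequence = NA`.
#' @export
pairwise_records <- function(cohort, n_readers = 3) {
  case_ids <- vapply(cohort, function(s) as.character(s$case_id), character(1))
  out <- list()
  for (cid in unique(case_ids)) {
    sets <- cohort[case_ids == cid]
    if (length(sets) < n_readers) {
      warn_segvar(sprintf("case %s has %d of %d readers; skipped",
                          cid, length(sets), n_readers),
                  "segvar_warning_missing_reader")
      next
    }
    out[[cid]] <- case_pairwise_records(sets)
  }
  if (length(out) == 0)
    return(empty_records())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

empty_records <- function() {
  data.frame(case_id = character(), reader_a = character(),
             reader_b = character(), structure = character(),
             sequence = character(), dsc = numeric(), jaccard = numeric(),
             hd_mm = numeric(), mda_mm = numeric(), vol_a_ml = numeric(),
             vol_b_ml = numeric(), stringsAsFactors = FALSE)
}

case_pairwise_records <- function(sets) {
  readers <- vapply(sets, function(s) as.character(s$reader_id), character(1))
  ord <- order(readers)
  sets <- sets[ord]; readers <- readers[ord]
  cid <- as.character(sets[[1]]$case_id)
  labels <- Reduce(intersect, lapply(sets, function(s) names(s$dil)))
  rows <- list()
  pair_idx <- utils::combn(length(sets), 2)
  for (p in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, p]; j <- pair_idx[2, p]
    add <- function(structure, sequence, ma, mb) {
      res <- tryCatch(compare_masks(ma, mb),
                      segvar_error_undefined_metric = function(e) NULL)
      if (is.null(res))
        res <- list(dsc = NA_real_, jaccard = NA_real_, hd_mm = NA_real_,
                    mda_mm = NA_real_, vol_a_ml = mask_volume_ml(ma),
                    vol_b_ml = mask_volume_ml(mb))
      data.frame(case_id = cid, reader_a = readers[i], reader_b = readers[j],
                 structure = structure, sequence = sequence,
                 dsc = res$dsc, jaccard = res$jaccard, hd_mm = res$hd_mm,
                 mda_mm = res$mda_mm, vol_a_ml = res$vol_a_ml,
                 vol_b_ml = res$vol_b_ml, stringsAsFactors = FALSE)
    }
    for (st in gland_structures())
      rows[[length(rows) + 1]] <- add(st, NA_character_,
                                      sets[[i]][[st]], sets[[j]][[st]])
    for (lab in labels)
      rows[[length(rows) + 1]] <- add("dil", lab,
                                      sets[[i]]$dil[[lab]], sets[[j]]$dil[[lab]])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

metric_columns <- function() c("dsc", "jaccard", "hd_mm", "mda_mm")

#' Per-sequence and per-reader-pair metric summaries
#'
#' Aggregates pairwise records into the per-sequence summary tables: one row
#' per (group, reader pair) plus an `"ALL"` row per group pooling every
#' (case, pair) value. Gland structures are grouped by structure name,
#' lesion rows by sequence label. Missing metric values are excluded from
#' that metric's mean/sd only; exclusion counts are reported.
#'
#' @param records data.frame from [pairwise_records()].
#' @return data.frame with columns `group, structure, sequence, reader_a,
#'   reader_b, n`, then `<metric>_mean`, `<metric>_sd`, `<metric>_n_missing`
#'   for each of dsc, jaccard, hd_mm, mda_mm.
#' @export
sequence_means <- function(records) {
  if (nrow(records) == 0)
    abort_segvar("no records to summarize", "segvar_error_empty_input")
  records$group <- ifelse(records$structure == "dil",
                          records$sequence, records$structure)
  records$pair <- paste(records$reader_a, records$reader_b, sep = "/")
  summarize <- function(df, reader_a, reader_b) {
    row <- data.frame(group = df$group[1], structure = df$structure[1],
                      sequence = df$sequence[1], reader_a = reader_a,
                      reader_b = reader_b, n = nrow(df),
                      stringsAsFactors = FALSE)
    for (m in metric_columns()) {
      v <- df[[m]]
      row[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_
      row[[paste0(m, "_n_missing")]] <- sum(is.na(v))
    }
    row
  }
  rows <- list()
  for (grp in unique(records$group)) {
    sub <- records[records$group == grp, ]
    for (pr in sort(unique(sub$pair))) {
      df <- sub[sub$pair == pr, ]
      rows[[length(rows) + 1]] <- summarize(df, df$reader_a[1], df$reader_b[1])
    }
    rows[[length(rows) + 1]] <- summarize(sub, "ALL", "ALL")
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("sequence_summary", class(out))
  out
}

#' Per-reader, per-sequence mean delineated volumes
#'
#' @param volumes data.frame with columns `case_id, reader_id, structure,
#'   sequence, vol_ml` (one row per delineated mask), e.g. from
#'   [case_volumes()].
#' @return data.frame `reader_id, structure, sequence, n, mean_vol_ml`.
#' @export
volume_summary <- function(volumes) {
  if (is.null(volumes) || nrow(volumes) == 0)
    abort_segvar("empty cohort: no volumes to summarize",
                 "segvar_error_empty_input")
  key <- interaction(volumes$reader_id, volumes$structure,
                     ifelse(is.na(volumes$sequence), "", volumes$sequence),
                     drop = TRUE)
  rows <- lapply(split(volumes, key), function(df) {
    data.frame(reader_id = df$reader_id[1], structure = df$structure[1],
               sequence = df$sequence[1], n = nrow(df),
               mean_vol_ml = mean(df$vol_ml), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$structure, out$sequence, out$reader_id), , drop = FALSE]
}

#' Extract per-mask volumes from structure sets
#'
#' @param cohort list of `structure_set` objects.
#' @return data.frame `case_id, reader_id, structure, sequence, vol_ml`.
#' @export
case_volumes <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    gl <- data.frame(case_id = as.character(s$case_id),
                     reader_id = as.character(s$reader_id),
                     structure = gland_structures(),
                     sequence = NA_character_,
                     vol_ml = vapply(gland_structures(),
                                     function(st) mask_volume_ml(s[[st]]), 0),
                     stringsAsFactors = FALSE)
    dl <- data.frame(case_id = as.character(s$case_id),
                     reader_id = as.character(s$reader_id),
                     structure = "dil", sequence = names(s$dil),
                     vol_ml = vapply(s$dil, mask_volume_ml, 0),
                     stringsAsFactors = FALSE)
    rbind(gl, dl)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Within-reader similarity between sequence labels
#'
#' For each reader and case, the DSC between that reader's lesion masks for
#' every pair of sequence labels, averaged over readers and cases into a
#' symmetric matrix with unit diagonal. Pairs where both masks are empty are
#' excluded; pairs with one empty mask contribute DSC 0.
#'
#' @param cohort list of `structure_set` objects, each containing all
#'   requested labels.
#' @param labels sequence labels to compare (default all 12).
#' @return symmetric numeric matrix with `labels` as dimnames.
#' @export
cross_sequence_similarity <- function(cohort, labels = all_sequence_labels()) {
  acc <- cross_sequence_accumulator(labels)
  for (s in cohort) acc$add(s)
  acc$result()
}

# Streaming accumulator so cohort-scale runs need not hold all masks.
cross_sequence_accumulator <- function(labels = all_sequence_labels()) {
  k <- length(labels)
  sums <- matrix(0, k, k, dimnames = list(labels, labels))
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  add <- function(s) {
    missing <- setdiff(labels, names(s$dil))
    if (length(missing))
      abort_segvar(sprintf("structure set lacks labels: %s",
                           paste(missing, collapse = ", ")),
                   "segvar_error_sequence_label")
    # crop all label masks to their joint bounding box once
    bb <- NULL
    for (lab in labels) bb <- bbox_union(bb, mask_bbox(s$dil[[lab]]$voxels, 0L))
    if (is.null(bb)) return(invisible(NULL))
    vox <- lapply(labels, function(lab) crop_voxels(s$dil[[lab]]$voxels, bb))
    cnt <- vapply(vox, sum, 0L)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      tot <- cnt[i] + cnt[j]
      if (tot == 0) next
      d <- 2 * sum(vox[[i]] & vox[[j]]) / tot
      sums[i, j] <<- sums[i, j] + d
      counts[i, j] <<- counts[i, j] + 1L
    }
    invisible(NULL)
  }
  result <- function() {
    m <- sums / pmax(counts, 1L)
    m <- m + t(m)
    m[(counts + t(counts)) == 0] <- NA_real_
    diag(m) <- 1
    m
  }
  list(add = add, result = result)
}
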