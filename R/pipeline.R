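# ---------------------------------------------------------------------------
# Pipeline orchestration: simulate -> metrics -> combine -> aggregate ->
# stats, with table outputs in the shape of the standard reporting tables.
# ---------------------------------------------------------------------------

#' Full statistical analysis of pairwise records
#'
#' Runs the complete statistical layer on aggregated records: per-sequence
#' and per-pair summaries, the between-sequence t-test matrix, the PI-RADS
#' group comparison, the Spearman screen of case features against per-case
#' mean DSC, the multivariate logistic fit on the Spearman-significant
#' features, and the reference power computation.
#'
#' @param records data.frame from [pairwise_records()].
#' @param volumes data.frame from [case_volumes()].
#' @param meta case metadata (`case_id, age, pirads, psa, isup`).
#' @param paired use paired between-sequence t-tests (default TRUE).
#' @param adjust p-value adjustment method (default "none").
#' @param power_spec list `mean_a, mean_b, sd, n, alpha` for the reference
#'   two-sample power computation.
#' @return list with `sequence_summary`, `volume_summary`, `case_matrix`,
#'   `ttest_matrix`, `pirads_tests`, `case_features`, `spearman`,
#'   `logistic`, `power`.
#' @export
analyze_records <- function(records, volumes, meta, paired = TRUE,
                            adjust = "none",
                            power_spec = list(mean_a = 0.55, mean_b = 0.50,
                                              sd = 0.08, n = 64,
                                              alpha = 0.05)) {
  summ <- sequence_means(records)
  vols <- volume_summary(volumes)
  cm <- dsc_case_matrix(records)
  tt <- ttest_between_sequences(cm, paired = paired, adjust = adjust)
  pir <- pirads_group_test(cm[, delineated_sequence_labels(), drop = FALSE],
                           meta)
  feats <- case_feature_table(records, volumes, meta)
  dsc <- feats$mean_dsc
  names(dsc) <- feats$case_id
  screen_feats <- feats[, c("age", "prostate_volume_ml", "lesion_volume_ml",
                            "pirads")]
  sp <- spearman_screen(dsc, screen_feats)
  sig <- sp$feature[!is.na(sp$p_value) & sp$p_value < 0.05]
  logit <- NULL
  if (length(sig) > 0) {
    lf <- screen_feats[, sig, drop = FALSE]
    # the grade enters the regression as the 5 vs <5 dichotomy, the grouping
    # used throughout the comparison layer
    if ("pirads" %in% names(lf)) lf$pirads <- as.integer(lf$pirads >= 5)
    logit <- logistic_multivariate(median_split(dsc), lf)
  }
  pw <- do.call(design_power, power_spec)
  list(sequence_summary = summ, volume_summary = vols, case_matrix = cm,
       ttest_matrix = tt, pirads_tests = pir, case_features = feats,
       spearman = sp, logistic = logit,
       power = c(power_spec, list(power = pw)))
}

# Per-case feature table: mean DSC pooled over the eight delineated labels,
# mean delineated prostate and lesion volumes, and metadata.
case_feature_table <- function(records, volumes, meta) {
  dil <- records[records$structure == "dil" &
                   records$sequence %in% delineated_sequence_labels(), ]
  dsc <- tapply(dil$dsc, dil$case_id, function(v) mean(v, na.rm = TRUE))
  pv <- volumes[volumes$structure == "prostate", ]
  pvol <- tapply(pv$vol_ml, pv$case_id, mean)
  lv <- volumes[volumes$structure == "dil" &
                  volumes$sequence %in% delineated_sequence_labels(), ]
  lvol <- tapply(lv$vol_ml, lv$case_id, mean)
  ids <- names(dsc)
  data.frame(case_id = ids, mean_dsc = as.numeric(dsc),
             prostate_volume_ml = as.numeric(pvol[ids]),
             lesion_volume_ml = as.numeric(lvol[ids]),
             age = meta$age[match(ids, as.character(meta$case_id))],
             pirads = meta$pirads[match(ids, as.character(meta$case_id))],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a cohort and analyze it in one pass
#'
#' Streams case by case (masks are dropped after each case's pairwise
#' comparisons), so cohort-scale runs stay memory-light. This is the
#' in-memory equivalent of [run_simulate()] followed by [run_analyze()].
#'
#' @param config a [simulation_config()].
#' @param progress print progress messages.
#' @return list: the [analyze_records()] outputs plus `records`, `volumes`,
#'   `cross_sequence`, `meta`, `amplitudes`.
#' @export
simulate_and_analyze <- function(config, progress = FALSE) {
  rec_chunks <- list()
  vol_chunks <- list()
  xacc <- cross_sequence_accumulator()
  collect <- function(cs) {
    rec_chunks[[length(rec_chunks) + 1]] <<- case_pairwise_records(cs$readers)
    vol_chunks[[length(vol_chunks) + 1]] <<- case_volumes(cs$readers)
    for (s in cs$readers) xacc$add(s)
  }
  sim <- generate_cohort(config, case_callback = collect, progress = progress)
  records <- do.call(rbind, c(rec_chunks, list(make.row.names = FALSE)))
  volumes <- do.call(rbind, c(vol_chunks, list(make.row.names = FALSE)))
  res <- analyze_records(records, volumes, sim$meta,
                         power_spec = list(mean_a = 0.55, mean_b = 0.50,
                                           sd = 0.08, n = config$n_cases,
                                           alpha = 0.05))
  c(res, list(records = records, volumes = volumes,
              cross_sequence = xacc$result(), meta = sim$meta,
              amplitudes = sim$amplitudes))
}

#' Simulate a cohort to disk
#'
#' Writes the standard cohort layout (`{case}/{reader}/{structure}.nii.gz`
#' mask files, `meta.csv`, `config_used.json`).
#'
#' @param config a [simulation_config()].
#' @param output_dir output directory.
#' @param progress print progress messages.
#' @return `output_dir`, invisibly.
#' @export
run_simulate <- function(config, output_dir, progress = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  generate_cohort(config, output_dir = output_dir, progress = progress)
  invisible(output_dir)
}

#' Analyze an on-disk cohort
#'
#' Reads `meta.csv` and the per-case mask files, streams the pairwise
#' comparisons, and writes the full report bundle: `pairwise.csv`,
#' `sequence_summary.csv`, `volume_summary.csv`, `cross_sequence_dsc.csv`,
#' `ttest_matrix.csv`, `pirads_tests.csv`, `spearman.csv`, `logistic.csv`,
#' `power.json` and `manifest.json` (seed-independent run metadata and
#' exclusion counts). Cases with missing reader files are excluded with a
#' warning and recorded in the manifest.
#'
#' @param input_dir cohort directory (layout of [run_simulate()]).
#' @param output_dir report directory.
#' @param paired,adjust between-sequence test options.
#' @param n_readers expected readers per case.
#' @return the [analyze_records()] result list, invisibly.
#' @export
run_analyze <- function(input_dir, output_dir, paired = TRUE,
                        adjust = "none", n_readers = 3) {
  meta_path <- file.path(input_dir, "meta.csv")
  meta <- load_case_meta(meta_path)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rec_chunks <- list(); vol_chunks <- list()
  xacc <- cross_sequence_accumulator()
  excluded <- character(0)
  rdrs <- NULL
  for (cid in meta$case_id) {
    cdir <- file.path(input_dir, cid)
    rdrs <- if (dir.exists(cdir)) sort(list.dirs(cdir, recursive = FALSE,
                                                 full.names = FALSE)) else character(0)
    sets <- list()
    ok <- TRUE
    for (r in rdrs) {
      s <- tryCatch(load_structure_set(input_dir, cid, r),
                    segvar_error_missing_file = function(e) NULL)
      if (is.null(s)) { ok <- FALSE; next }
      sets[[length(sets) + 1]] <- s
    }
    if (!ok || length(sets) < n_readers) {
      warn_segvar(sprintf("case %s incomplete (%d of %d readers); excluded",
                          cid, length(sets), n_readers),
                  "segvar_warning_missing_reader")
      excluded <- c(excluded, cid)
      next
    }
    rec_chunks[[length(rec_chunks) + 1]] <- case_pairwise_records(sets)
    vol_chunks[[length(vol_chunks) + 1]] <- case_volumes(sets)
    for (s in sets) xacc$add(s)
  }
  if (length(rec_chunks) == 0)
    abort_segvar(sprintf("no complete cases under %s", input_dir),
                 "segvar_error_layout")
  records <- do.call(rbind, c(rec_chunks, list(make.row.names = FALSE)))
  volumes <- do.call(rbind, c(vol_chunks, list(make.row.names = FALSE)))
  res <- analyze_records(records, volumes, meta, paired = paired,
                         adjust = adjust)
  res$cross_sequence <- xacc$result()
  write_report_bundle(res, records, output_dir, excluded = excluded,
                      input_dir = input_dir)
  invisible(res)
}

round_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_report_bundle <- function(res, records, output_dir, excluded,
                                input_dir) {
  wr <- function(df, name) write.csv(round_df(df),
                                     file.path(output_dir, name),
                                     row.names = FALSE)
  wr(records, "pairwise.csv")
  wr(res$sequence_summary, "sequence_summary.csv")
  wr(res$volume_summary, "volume_summary.csv")
  write.csv(round(res$cross_sequence, 4),
            file.path(output_dir, "cross_sequence_dsc.csv"))
  write.csv(round(res$ttest_matrix, 4),
            file.path(output_dir, "ttest_matrix.csv"))
  wr(res$pirads_tests, "pirads_tests.csv")
  wr(res$spearman, "spearman.csv")
  if (!is.null(res$logistic) && res$logistic$converged)
    wr(res$logistic$coefficients, "logistic.csv")
  else
    write.csv(data.frame(note = "logistic fit not reported (no significant features or non-convergence)"),
              file.path(output_dir, "logistic.csv"), row.names = FALSE)
  jsonlite::write_json(res$power, file.path(output_dir, "power.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(res, file.path(output_dir, "analysis_full.rds"))
  manifest <- list(
    input_dir = input_dir,
    n_cases_analyzed = length(unique(records$case_id)),
    n_records = nrow(records),
    excluded_cases = as.list(excluded),
    n_excluded = length(excluded),
    paired_ttests = isTRUE(attr(res$ttest_matrix, "paired")),
    package_version = as.character(utils::packageVersion("segvar")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Render a plain-text summary of an analysis report bundle
#'
#' @param output_dir directory written by [run_analyze()].
#' @param file optional path to write the summary to; otherwise printed.
#' @return the summary lines, invisibly.
#' @export
run_report <- function(output_dir, file = NULL) {
  need <- c("sequence_summary.csv", "pirads_tests.csv", "power.json")
  for (f in need)
    if (!file.exists(file.path(output_dir, f)))
      abort_segvar(sprintf("missing report input: %s", f),
                   "segvar_error_missing_file")
  summ <- read.csv(file.path(output_dir, "sequence_summary.csv"))
  pir <- read.csv(file.path(output_dir, "pirads_tests.csv"))
  pw <- jsonlite::read_json(file.path(output_dir, "power.json"))
  lines <- c("Inter-reader contour variability report",
             "=======================================", "")
  all_rows <- summ[summ$reader_a == "ALL", ]
  lines <- c(lines, "Mean DSC (all reader pairs pooled):",
             sprintf("  %-18s %5.3f (sd %5.3f, n %d)", all_rows$group,
                     all_rows$dsc_mean, all_rows$dsc_sd, all_rows$n), "")
  lines <- c(lines, "PI-RADS 5 vs <5 (per-sequence t-tests):",
             sprintf("  %-12s p = %6.4f (means %5.3f vs %5.3f)",
                     pir$sequence, pir$p_value, pir$mean_pirads5,
                     pir$mean_other), "")
  lines <- c(lines, sprintf(
    "Design power: %.3f for DSC %.2f vs %.2f, sd %.2f, n %d, alpha %.2f",
    pw$power, pw$mean_a, pw$mean_b, pw$sd, pw$n, pw$alpha))
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
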