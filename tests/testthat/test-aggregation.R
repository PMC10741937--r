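# Build a small complete cohort of identical or controlled reader sets.
make_reader_set <- function(case_id, reader_id, g, dil_masks, prost, tz, pz) {
  structure_set(case_id, reader_id, prostate = prost, tz = tz, pz = pz,
                dil = dil_masks)
}

identical_cohort <- function(n_cases = 2, n_readers = 3) {
  g <- make_geom(c(16, 16, 8), c(1, 1, 2))
  prost <- cube_mask(g, c(2, 2, 2), c(14, 14, 7))
  tz <- cube_mask(g, c(5, 5, 3), c(11, 11, 6))
  pz <- binary_mask(prost$voxels & !tz$voxels, g)
  set.seed(42)
  out <- list()
  for (ci in seq_len(n_cases)) {
    dil <- list()
    for (lab in delineated_sequence_labels())
      dil[[lab]] <- cube_mask(g, c(6, 6, 3), c(9 + ci %% 2, 9, 5))
    for (ri in seq_len(n_readers)) {
      s <- make_reader_set(sprintf("c%d", ci), sprintf("R%d", ri), g,
                           dil, prost, tz, pz)
      out[[length(out) + 1]] <- build_union_sets(s)
    }
  }
  out
}

test_that("record counts follow the cases x pairs x structures formula", {
  cohort <- identical_cohort(n_cases = 2)
  rec <- pairwise_records(cohort)
  # 2 cases x 3 pairs x (3 gland structures + 12 lesion labels)
  expect_equal(nrow(rec), 2 * 3 * 15)
  expect_equal(sum(rec$structure == "dil"), 2 * 3 * 12)
  expect_equal(sum(rec$structure == "prostate"), 6)
})

test_that("identical readers give unit DSC everywhere", {
  rec <- pairwise_records(identical_cohort())
  expect_true(all(rec$dsc == 1))
  expect_true(all(rec$hd_mm == 0))
  expect_true(all(rec$mda_mm == 0))
})

test_that("a case with a missing reader is skipped with a warning", {
  cohort <- identical_cohort(n_cases = 2)
  cohort <- cohort[-1]  # drop one reader of case 1
  expect_warning(rec <- pairwise_records(cohort),
                 class = "segvar_warning_missing_reader")
  expect_equal(unique(rec$case_id), "c2")
})

test_that("aggregation is invariant to case order", {
  cohort <- identical_cohort(n_cases = 3)
  rec1 <- pairwise_records(cohort)
  rec2 <- pairwise_records(rev(cohort))
  s1 <- sequence_means(rec1)
  s2 <- sequence_means(rec2)
  key <- function(df) paste(df$group, df$reader_a, df$reader_b)
  s2 <- s2[match(key(s1), key(s2)), ]
  expect_equal(s1$dsc_mean, s2$dsc_mean)
})

test_that("sequence means and sds match hand computation", {
  rec <- empty_rec <- pairwise_records(identical_cohort(n_cases = 2))
  two <- rec[rec$sequence %in% "T2" | (is.na(rec$sequence) &
                                         rec$structure == "prostate"), ]
  two <- two[two$reader_a == "R1" & two$reader_b == "R2" &
               two$structure == "dil", ]
  two$dsc <- c(0.4, 0.6)
  out <- sequence_means(two)
  pooled <- out[out$reader_a == "ALL", ]
  expect_equal(pooled$dsc_mean, 0.5)
  expect_equal(pooled$dsc_sd, sd(c(0.4, 0.6)))
  # the pooled mean lies within the per-pair range
  full <- sequence_means(rec)
  for (grp in unique(full$group)) {
    sub <- full[full$group == grp, ]
    pool <- sub$dsc_mean[sub$reader_a == "ALL"]
    per <- sub$dsc_mean[sub$reader_a != "ALL"]
    expect_gte(pool, min(per) - 1e-12)
    expect_lte(pool, max(per) + 1e-12)
  }
})

test_that("missing metric values are excluded and counted per metric", {
  rec <- pairwise_records(identical_cohort(n_cases = 2))
  rec$hd_mm[rec$sequence %in% "DCE" & rec$case_id == "c1"] <- NA
  out <- sequence_means(rec)
  dce <- out[out$group == "DCE" & out$reader_a == "ALL", ]
  expect_equal(dce$hd_mm_n_missing, 3)
  expect_equal(dce$hd_mm_mean, 0)  # remaining values are 0
  expect_equal(dce$dsc_n_missing, 0)
})

test_that("volume summaries aggregate per reader and sequence", {
  cohort <- identical_cohort(n_cases = 2)
  vols <- case_volumes(cohort)
  vs <- volume_summary(vols)
  r1 <- vs[vs$reader_id == "R1" & vs$structure == "dil", ]
  # union sets dominate their components
  expect_gte(r1$mean_vol_ml[r1$sequence == "T2+ADC"],
             r1$mean_vol_ml[r1$sequence == "T2"])
  expect_error(volume_summary(vols[0, ]), class = "segvar_error_empty_input")
})

test_that("cross-sequence similarity is a symmetric unit-diagonal matrix", {
  cohort <- identical_cohort(n_cases = 2)
  m <- cross_sequence_similarity(cohort)
  expect_equal(dim(m), c(12, 12))
  expect_true(all(diag(m) == 1))
  expect_equal(m, t(m))
  # identical masks for all labels: all-ones matrix
  expect_true(all(m == 1))
})
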