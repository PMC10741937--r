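#' Per-case per-sequence DSC matrix
#'
#' Collapses pairwise lesion records to one DSC value per case and sequence
#' (the mean over the reader pairs of that case), the unit of analysis for
#' the between-sequence tests and the correlation screen.
#'
#' @param records data.frame from [pairwise_records()].
#' @param metric which metric column to collapse (default `"dsc"`).
#' @return numeric matrix, cases x sequence labels.
#' @export
dsc_case_matrix <- function(records, metric = "dsc") {
  dil <- records[records$structure == "dil", ]
  if (nrow(dil) == 0)
    abort_segvar("no lesion records", "segvar_error_empty_input")
  cases <- sort(unique(dil$case_id))
  labs <- intersect(all_sequence_labels(), unique(dil$sequence))
  m <- matrix(NA_real_, length(cases), length(labs),
              dimnames = list(cases, labs))
  agg <- aggregate(dil[[metric]],
                   by = list(case_id = dil$case_id, sequence = dil$sequence),
                   FUN = function(v) mean(v, na.rm = TRUE))
  for (r in seq_len(nrow(agg)))
    m[agg$case_id[r], agg$sequence[r]] <- agg$x[r]
  m[is.nan(m)] <- NA_real_
  m
}

#' Between-sequence t-test matrix
#'
#' Two-sided Student t-test of per-case DSC between every pair of sequence
#' labels. Defaults to the paired test (the same cases are delineated under
#' every sequence); set `paired = FALSE` for the unpaired variant. The
#' diagonal is 1 and the matrix is symmetric. Degenerate pairs (zero
#' variance, e.g. a label tested against itself) give p = 1 and are counted
#' in the `"n_degenerate"` attribute.
#'
#' @param case_matrix cases x sequences matrix from [dsc_case_matrix()].
#' @param paired use the paired t-test (default TRUE).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, no multiple-testing correction).
#' @return symmetric matrix of p-values with a `"n_degenerate"` attribute.
#' @export
ttest_between_sequences <- function(case_matrix, paired = TRUE,
                                    adjust = "none") {
  labs <- colnames(case_matrix)
  k <- length(labs)
  if (nrow(case_matrix) < 2)
    abort_segvar("need >= 2 cases per sequence", "segvar_error_empty_input")
  p <- matrix(1, k, k, dimnames = list(labs, labs))
  degenerate <- 0L
  raw <- c()
  idx <- which(upper.tri(p), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    a <- case_matrix[, i]; b <- case_matrix[, j]
    ok <- complete.cases(a, b)
    pv <- tryCatch(
      t.test(a[ok], b[ok], paired = paired, var.equal = !paired)$p.value,
      error = function(e) NaN)
    if (!is.finite(pv)) {  # zero-variance (identical) inputs
      degenerate <- degenerate + 1L
      pv <- 1
    }
    raw <- c(raw, pv)
  }
  if (adjust != "none") raw <- stats::p.adjust(raw, method = adjust)
  for (r in seq_len(nrow(idx))) {
    p[idx[r, 1], idx[r, 2]] <- raw[r]
    p[idx[r, 2], idx[r, 1]] <- raw[r]
  }
  attr(p, "n_degenerate") <- degenerate
  attr(p, "paired") <- paired
  p
}

#' PI-RADS group comparison per sequence
#'
#' Two-sided unpaired t-test of per-case DSC between PI-RADS 5 and
#' PI-RADS < 5 cases, for each sequence label.
#'
#' @param case_matrix cases x sequences matrix from [dsc_case_matrix()].
#' @param meta metadata data.frame with `case_id` and `pirads`.
#' @return data.frame `sequence, statistic, p_value, n_pirads5, n_other,
#'   mean_pirads5, mean_other`.
#' @export
pirads_group_test <- function(case_matrix, meta) {
  pir <- meta$pirads[match(rownames(case_matrix), as.character(meta$case_id))]
  if (anyNA(pir))
    abort_segvar("metadata is missing cases present in the records",
                 "segvar_error_metadata")
  g5 <- pir == 5
  if (!any(g5))
    abort_segvar("group 'PI-RADS 5' is empty", "segvar_error_empty_group")
  if (all(g5))
    abort_segvar("group 'PI-RADS < 5' is empty", "segvar_error_empty_group")
  rows <- lapply(colnames(case_matrix), function(lab) {
    a <- case_matrix[g5, lab]; b <- case_matrix[!g5, lab]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    data.frame(sequence = lab,
               statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               n_pirads5 = length(a),
               n_other = length(b), mean_pirads5 = mean(a),
               mean_other = mean(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Spearman correlation screen of case features against agreement
#'
#' Rank correlation (average-rank tie handling, asymptotic p-values) of each
#' feature with the per-case mean DSC. Constant features yield an
#' undefined-correlation entry (`NA` with a note) rather than failing the
#' whole screen.
#'
#' @param dsc named numeric vector of per-case mean DSC (names = case ids).
#' @param features data.frame of per-case features (rows aligned with
#'   `dsc`), typically age, prostate volume, lesion volume and PI-RADS.
#' @return data.frame `feature, rho, p_value, n, note`.
#' @export
spearman_screen <- function(dsc, features) {
  if (length(dsc) < 3)
    abort_segvar("need >= 3 cases", "segvar_error_empty_input")
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    ok <- !is.na(x) & !is.na(dsc)
    if (length(unique(x[ok])) < 2)
      return(data.frame(feature = f, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), note = "constant feature: correlation undefined",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      cor.test(x[ok], dsc[ok], method = "spearman", exact = FALSE))
    data.frame(feature = f, rho = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Multivariate logistic regression of dichotomized agreement
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' outcome on the supplied features, with per-feature Wald p-values. The
#' intended outcome is the per-case mean DSC dichotomized at the cohort
#' median (use [median_split()]), recorded in `outcome_definition`.
#' Separation or non-convergence is flagged and no coefficients are
#' reported.
#'
#' @param outcome logical/0-1 vector with both classes present.
#' @param features data.frame of per-case predictors.
#' @param outcome_definition description string stored with the fit.
#' @return an object of class `logistic_fit`: list with `coefficients`
#'   (data.frame feature/estimate/se/p_value, NULL unless converged),
#'   `converged`, `outcome_definition`, `n`.
#' @export
logistic_multivariate <- function(outcome, features,
                                  outcome_definition =
                                    "per-case mean DSC above cohort median") {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) != 2)
    abort_segvar("outcome must contain both classes", "segvar_error_outcome")
  df <- cbind(data.frame(.y = y), features)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  converged <- fit$converged && !separated &&
    all(abs(coef(fit)[-1]) < 1e3, na.rm = TRUE)
  coefs <- NULL
  if (converged) {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(feature = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], p_value = sm[, 4],
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(coefficients = coefs, converged = converged,
                 outcome_definition = outcome_definition, n = nrow(df)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> outcome: %s; n = %d; converged: %s\n",
              x$outcome_definition, x$n, x$converged))
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Median split of a numeric vector
#'
#' @param x numeric vector.
#' @return logical vector, `x > median(x)`.
#' @export
median_split <- function(x) x > median(x, na.rm = TRUE)

#' Power of a two-sided two-sample t-test design
#'
#' Noncentral-t power for detecting a mean DSC difference `mean_a - mean_b`
#' with common standard deviation `sd`, `n` cases per group, at two-sided
#' level `alpha`.
#'
#' @param mean_a,mean_b group means (e.g. DSC under two imaging protocols).
#' @param sd common standard deviation (> 0).
#' @param n cases per group (>= 2).
#' @param alpha two-sided type-1 error, in (0, 1).
#' @return power in \[0, 1\].
#' @examples
#' design_power(0.55, 0.50, sd = 0.08, n = 64) # >= 0.80
#' @export
design_power <- function(mean_a, mean_b, sd, n, alpha = 0.05) {
  if (sd <= 0) abort_segvar("sd must be > 0", "segvar_error_power_spec")
  if (n < 2) abort_segvar("n must be >= 2", "segvar_error_power_spec")
  if (alpha <= 0 || alpha >= 1)
    abort_segvar("alpha must be in (0,1)", "segvar_error_power_spec")
  delta <- abs(mean_a - mean_b)
  if (delta == 0) return(alpha)
  power.t.test(n = n, delta = delta, sd = sd, sig.level = alpha,
               type = "two.sample", alternative = "two.sided")$power
}
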