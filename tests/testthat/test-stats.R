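make_case_matrix <- function(n = 20, seed = 1, shift = NULL) {
  set.seed(seed)
  labs <- all_sequence_labels()
  m <- matrix(rnorm(n * length(labs), 0.5, 0.08), n, length(labs),
              dimnames = list(sprintf("case%02d", 1:n), labs))
  if (!is.null(shift)) m[, names(shift)] <- sweep(
    m[, names(shift), drop = FALSE], 2, shift, "+")
  m
}

test_that("the t-test matrix is symmetric with unit diagonal", {
  cm <- make_case_matrix()
  p <- ttest_between_sequences(cm)
  expect_equal(dim(p), c(12, 12))
  expect_true(all(diag(p) == 1))
  expect_equal(p, t(p))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("identical per-case values give p = 1 and are counted degenerate", {
  cm <- make_case_matrix()
  cm[, "ADC"] <- cm[, "T2"]
  p <- ttest_between_sequences(cm, paired = TRUE)
  expect_equal(p["T2", "ADC"], 1)
  expect_gte(attr(p, "n_degenerate"), 1)
})

test_that("paired p-values match the textbook t-test on printed samples", {
  a <- c(0.52, 0.47, 0.60, 0.55, 0.43, 0.58, 0.50, 0.49)
  b <- c(0.35, 0.40, 0.42, 0.30, 0.38, 0.36, 0.41, 0.33)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(tstat), df = length(d) - 1)
  cm <- make_case_matrix(n = 8)
  cm[, "T2"] <- a; cm[, "DCE"] <- b
  p <- ttest_between_sequences(cm, paired = TRUE)
  expect_equal(p["T2", "DCE"], p_hand, tolerance = 1e-12)
})

test_that("a strong shift is detected while a null is not", {
  cm <- make_case_matrix(n = 40, seed = 3, shift = c(DCE = -0.15))
  p <- ttest_between_sequences(cm)
  expect_lt(p["T2", "DCE"], 0.001)
  expect_gt(p["T2", "ADC"], 0.05)
  holm <- ttest_between_sequences(cm, adjust = "holm")
  expect_gte(holm["T2", "ADC"], p["T2", "ADC"])
})

test_that("the PI-RADS group test separates boosted groups and validates input", {
  cm <- make_case_matrix(n = 30, seed = 9)
  meta <- data.frame(case_id = rownames(cm),
                     pirads = rep(c(5L, 4L), c(20, 10)))
  cm[1:20, ] <- cm[1:20, ] + 0.12
  out <- pirads_group_test(cm[, delineated_sequence_labels()], meta)
  expect_equal(nrow(out), 8)
  expect_true(all(out$p_value < 0.05))
  expect_true(all(out$mean_pirads5 > out$mean_other))
  meta5 <- meta; meta5$pirads <- 5L
  expect_error(pirads_group_test(cm, meta5), class = "segvar_error_empty_group")
  meta0 <- meta; meta0$pirads <- 4L
  expect_error(pirads_group_test(cm, meta0), class = "segvar_error_empty_group")
})

test_that("spearman screen matches rank computation and handles ties/constants", {
  dsc <- c(a = 0.3, b = 0.4, c = 0.45, d = 0.6, e = 0.7)
  feats <- data.frame(up = 1:5, down = 5:1, tied = c(1, 1, 2, 2, 3),
                      flat = rep(2, 5))
  out <- spearman_screen(dsc, feats)
  expect_equal(out$rho[out$feature == "up"], 1)
  expect_equal(out$rho[out$feature == "down"], -1)
  # average-rank tie handling oracle
  rho_hand <- cor(rank(c(1, 1, 2, 2, 3)), rank(dsc))
  expect_equal(out$rho[out$feature == "tied"], rho_hand, tolerance = 1e-12)
  expect_true(is.na(out$rho[out$feature == "flat"]))
  expect_match(out$note[out$feature == "flat"], "constant")
  expect_error(spearman_screen(dsc[1:2], feats[1:2, ]),
               class = "segvar_error_empty_input")
})

test_that("logistic regression recovers a strong generative coefficient", {
  set.seed(21)
  n <- 120
  x <- rnorm(n)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  fit <- logistic_multivariate(y, data.frame(x = x, z = z))
  expect_true(fit$converged)
  cx <- fit$coefficients[fit$coefficients$feature == "x", ]
  expect_gt(cx$estimate, 0)
  expect_lt(cx$p_value, 0.01)
  cz <- fit$coefficients[fit$coefficients$feature == "z", ]
  expect_gt(cz$p_value, 0.05)
  expect_lt(abs(cz$estimate), abs(cx$estimate))
})

test_that("perfect separation is flagged instead of reported", {
  y <- rep(c(0, 1), each = 20)
  x <- c(rnorm(20, -3), rnorm(20, 3))
  fit <- logistic_multivariate(y, data.frame(x = x))
  expect_false(fit$converged)
  expect_null(fit$coefficients)
  expect_error(logistic_multivariate(rep(1, 10), data.frame(x = rnorm(10))),
               class = "segvar_error_outcome")
})

test_that("design power matches the noncentral-t formulation and its limits", {
  expect_equal(design_power(0.5, 0.5, 0.08, 64), 0.05)
  expect_gte(design_power(0.55, 0.50, 0.08, 64), 0.80)
  expect_equal(design_power(1.0, 0.2, 0.08, 64), 1, tolerance = 1e-6)
  expect_equal(design_power(0.55, 0.50, 0.08, 64, alpha = 0.05),
               power.t.test(n = 64, delta = 0.05, sd = 0.08,
                            sig.level = 0.05)$power)
})

test_that("design power is monotone in n, effect size and sd", {
  ns <- c(10, 20, 40, 80, 160)
  pw_n <- vapply(ns, function(n) design_power(0.55, 0.5, 0.08, n), 0)
  expect_true(all(diff(pw_n) > 0))
  effects <- seq(0.01, 0.10, by = 0.01)
  pw_e <- vapply(effects, function(e) design_power(0.5 + e, 0.5, 0.08, 64), 0)
  expect_true(all(diff(pw_e) > 0))
  sds <- c(0.05, 0.08, 0.12, 0.2)
  pw_s <- vapply(sds, function(s) design_power(0.55, 0.5, s, 64), 0)
  expect_true(all(diff(pw_s) < 0))
  expect_error(design_power(0.5, 0.4, 0, 64), class = "segvar_error_power_spec")
  expect_error(design_power(0.5, 0.4, 0.08, 1), class = "segvar_error_power_spec")
})
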