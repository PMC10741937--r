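make_series <- function(signal_fn, nt = 20, dt = 5, shape = c(4, 4, 3)) {
  g <- make_geom(shape)
  ts <- (seq_len(nt) - 1) * dt
  frames <- array(0, c(shape, nt))
  for (k in seq_len(nt)) frames[, , , k] <- signal_fn(ts[k])
  dce_series(frames, ts, g)
}

test_that("dce_series validates its invariants", {
  g <- make_geom(c(4, 4, 3))
  fr <- array(1, c(4, 4, 3, 5))
  expect_error(dce_series(fr, c(0, 5, 10, 15, 15), g),
               class = "segvar_error_dce_series")
  expect_error(dce_series(fr[, , , 1:2], c(0, 5), g),
               class = "segvar_error_dce_series")
  expect_error(dce_series(array(1, c(4, 4, 4, 5)), (0:4) * 5, g),
               class = "segvar_error_geometry")
})

test_that("baseline is the mean of pre-contrast frames", {
  s <- make_series(function(t) 7)
  expect_true(all(baseline_estimate(s, 3) == 7))
  s2 <- make_series(function(t) 10 + t / 2.5, nt = 5)  # frames 10,12,14,...
  expect_true(all(abs(baseline_estimate(s2, 3) - 12) < 1e-12))
  expect_error(baseline_estimate(s2, 5), class = "segvar_error_baseline_range")
  expect_error(baseline_estimate(s2, 0), class = "segvar_error_baseline_range")
})

test_that("bolus arrival detection finds steps, ramps and the fallback", {
  step <- make_series(function(t) if (t >= 20) 120 else 100)
  expect_equal(detect_bolus_arrival(step, 0.1, n_baseline = 3), 5L)
  flat <- make_series(function(t) 100)
  expect_equal(detect_bolus_arrival(flat, 0.1, n_baseline = 3), 4L)
  ramp <- make_series(function(t) 100 + t)  # +5 per frame over baseline 105
  expect_equal(detect_bolus_arrival(ramp, 0.1, n_baseline = 3),
               which((100 + (0:19) * 5) > 105 * 1.1)[1])
})

test_that("IAUCG integrates relative enhancement over the window", {
  # signal equal to baseline: zero map
  flat <- make_series(function(t) 50)
  m0 <- compute_iaucg(flat, arrival = 4, window_s = 60, n_baseline = 3)
  expect_true(all(m0$values == 0))
  # unit relative-enhancement step lasting the whole window: area = 60
  step <- make_series(function(t) if (t >= 15) 200 else 100)
  ms <- compute_iaucg(step, arrival = 4, window_s = 60, n_baseline = 3)
  expect_true(all(abs(ms$values - 60) < 1e-9))
  # linear enhancement 0 -> 1 over the 60 s window: triangle area = 30
  t0 <- 15
  lin <- make_series(function(t) 100 * (1 + pmax(0, pmin(t - t0, 60)) / 60))
  ml <- compute_iaucg(lin, arrival = 4, window_s = 60, n_baseline = 3)
  expect_true(all(abs(ml$values - 30) < 1e-9))
})

test_that("IAUCG is linear in enhancement and additive over windows", {
  set.seed(2)
  shape <- c(3, 3, 2); nt <- 18
  g <- make_geom(shape)
  ts <- (seq_len(nt) - 1) * 5
  base <- array(100, c(shape, nt))
  enh <- array(0, c(shape, nt))
  for (k in 5:nt) enh[, , , k] <- array(runif(prod(shape), 0, 50), shape)
  s1 <- dce_series(base + enh, ts, g)
  s3 <- dce_series(base + 3 * enh, ts, g)
  m1 <- compute_iaucg(s1, 5, 40, 3)$values
  m3 <- compute_iaucg(s3, 5, 40, 3)$values
  expect_equal(m3, 3 * m1, tolerance = 1e-9)
  # window additivity at interior cut points (piecewise-linear integrand)
  a <- compute_iaucg(s1, 5, 17, 3)$values
  full <- compute_iaucg(s1, 5, 42, 3)$values
  s0 <- as.vector(baseline_estimate(s1, 3))
  enh_rel <- (matrix(s1$frames, ncol = nt) - s0) / s0
  w2 <- segvar:::trapezoid_weights(ts, ts[5] + 17, ts[5] + 42)
  b <- array(enh_rel %*% w2, shape)
  expect_equal(a + b, full, tolerance = 1e-9)
})

test_that("zero baseline flags voxels and long windows truncate", {
  g <- make_geom(c(2, 2, 2))
  ts <- (0:9) * 5
  fr <- array(100, c(2, 2, 2, 10))
  fr[1, 1, 1, ] <- 0
  s <- dce_series(fr, ts, g)
  m <- compute_iaucg(s, 4, 20, 3)
  expect_true(is.na(m$values[1, 1, 1]))
  expect_false(anyNA(m$values[-1]))
  expect_warning(compute_iaucg(s, 8, 60, 3),
                 class = "segvar_warning_window_truncated")
})
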