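test_that("ground-truth anatomy is reproducible and well-formed", {
  cfg <- tiny_config()
  g1 <- generate_gland(cfg, 12345)
  g2 <- generate_gland(cfg, 12345)
  expect_identical(g1$gland$voxels, g2$gland$voxels)
  # zones partition the gland
  expect_identical(g1$gland$voxels, g1$tz$voxels | g1$pz$voxels)
  expect_false(any(g1$tz$voxels & g1$pz$voxels))
  # rasterized volume near the sampled target (coarse unit-test grid)
  expect_lt(abs(mask_volume_ml(g1$gland) - g1$gland_volume_ml) /
              g1$gland_volume_ml, 0.15)
  # at the study-scale (0.5, 0.5, 3) mm grid the bound tightens to 10%
  cfg_full <- simulation_config(seed = 3)
  gf <- generate_gland(cfg_full, 77)
  expect_lt(abs(mask_volume_ml(gf$gland) - gf$gland_volume_ml) /
              gf$gland_volume_ml, 0.10)
})

test_that("lesions are placed inside the gland with controlled volumes", {
  cfg <- tiny_config()
  gl <- generate_gland(cfg, 99)
  les <- generate_lesion(cfg, 99, gl, volume_ml = 3)
  expect_true(all(!les$lesion$voxels | gl$gland$voxels))
  expect_gt(mask_volume_ml(les$lesion), 0.5)
  # cohort-scale volume check against the log-normal target mean of 3 mL,
  # at the study-scale grid where rasterization error is negligible
  cfg_full <- simulation_config(seed = 3)
  vols <- vapply(1:40, function(i) {
    gli <- generate_gland(cfg_full, 2000 + i)
    mask_volume_ml(generate_lesion(cfg_full, 2000 + i, gli)$lesion)
  }, 0)
  expect_lt(abs(mean(vols) - 3), 0.5)
})

test_that("PI-RADS follows jittered volume rank with exact counts", {
  cfg <- tiny_config(n_cases = 16, pirads_counts = c(`3` = 3, `4` = 4, `5` = 9))
  meta <- segvar:::sample_case_meta(cfg)
  expect_equal(unname(table(meta$pirads)[c("3", "4", "5")]), c(3L, 4L, 9L),
               ignore_attr = TRUE)
  expect_gt(mean(meta$lesion_volume_ml[meta$pirads == 5]),
            mean(meta$lesion_volume_ml[meta$pirads == 3]))
})

test_that("reader delineation is deterministic and exact at zero noise", {
  cfg <- tiny_config()
  gl <- generate_gland(cfg, 7)
  sdf <- segvar:::sdf_from_voxels(gl$gland$voxels, cfg$geometry$spacing)
  none <- reader_noise_model(translation_sd_mm = 0, scale_sd = 0,
                             boundary_correlation_mm = 5)
  m0 <- simulate_reader_delineation(sdf, cfg$geometry, none, amplitude = 0,
                                    seed = 3, center = gl$center)
  expect_identical(m0$voxels, gl$gland$voxels)
  noisy <- reader_noise_model()
  m1 <- simulate_reader_delineation(sdf, cfg$geometry, noisy, 2, seed = 5,
                                    center = gl$center)
  m2 <- simulate_reader_delineation(sdf, cfg$geometry, noisy, 2, seed = 5,
                                    center = gl$center)
  expect_identical(m1$voxels, m2$voxels)
  expect_false(identical(m1$voxels, gl$gland$voxels))
})

test_that("expected pairwise DSC decreases with field amplitude", {
  cfg <- tiny_config()
  set.seed(1)
  cal <- segvar:::make_dsc_calibrator(
    segvar:::lesion_shape_sampler(cfg), cfg$geometry, cfg$noise,
    n_mc = 25, seed = 4)
  amps <- c(0, 1, 2.5, 5)
  dscs <- vapply(amps, cal$mean_dsc, 0)
  expect_true(all(diff(dscs) < 0))
})

test_that("noise calibration hits its target and handles the edge cases", {
  cfg <- tiny_config()
  set.seed(2)
  expect_equal(calibrate_noise(1.0, segvar:::lesion_shape_sampler(cfg),
                               cfg$geometry, cfg$noise, n_mc = 5, seed = 1), 0)
  set.seed(2)
  cal <- segvar:::make_dsc_calibrator(
    segvar:::lesion_shape_sampler(cfg), cfg$geometry, cfg$noise,
    n_mc = 60, seed = 8)
  a55 <- cal$amplitude_for(0.55)
  expect_gt(a55, 0)
  expect_lt(abs(cal$mean_dsc(a55) - 0.55), 0.02)
  a35 <- cal$amplitude_for(0.35)
  expect_gt(a35, a55)  # lower target needs larger amplitude
  expect_error(cal$amplitude_for(0.999),
               class = "segvar_error_unreachable_target")
})

test_that("a small cohort reproduces its structure deterministically", {
  cfg <- tiny_config(n_cases = 3, pirads_counts = c(`3` = 1, `4` = 1, `5` = 1))
  sim1 <- generate_cohort(cfg)
  sim2 <- generate_cohort(cfg)
  expect_equal(length(sim1$cases), 3)
  expect_identical(sim1$meta, sim2$meta)
  expect_identical(sim1$cases[[2]]$readers[[1]]$dil$T2$voxels,
                   sim2$cases[[2]]$readers[[1]]$dil$T2$voxels)
  s <- sim1$cases[[1]]$readers[[1]]
  expect_setequal(names(s$dil), all_sequence_labels())
  # lesion masks overlap the prostate delineation region
  expect_true(all(!sim1$cases[[1]]$readers[[1]]$tz$voxels |
                    sim1$cases[[1]]$readers[[1]]$prostate$voxels))
})

test_that("the simulated DCE series behaves like its generative model", {
  g <- make_geom(c(12, 12, 4), c(1, 1, 3))
  gl <- cube_mask(g, c(3, 3, 1), c(10, 10, 4))
  les <- cube_mask(g, c(5, 5, 2), c(8, 8, 3))
  s1 <- generate_dce_series(les, gl, seed = 5, n_frames = 30)
  s2 <- generate_dce_series(les, gl, seed = 5, n_frames = 30)
  expect_identical(s1$frames, s2$frames)
  # no enhancement and no noise: flat series, zero IAUCG
  s0 <- generate_dce_series(les, gl, seed = 1, n_frames = 20,
                            amplitudes = c(lesion = 0, gland = 0,
                                           background = 0), noise_sd = 0)
  m0 <- compute_iaucg(s0, detect_bolus_arrival(s0, n_baseline = 4), 60, 4)
  expect_true(all(abs(m0$values) < 1e-12))
  # lesion enhances above background at default effect sizes
  arr <- detect_bolus_arrival(s1, n_baseline = 4, roi = gl)
  m <- compute_iaucg(s1, arr, 60, 4)
  expect_gt(mean(m$values[les$voxels]),
            mean(m$values[!gl$voxels]))
})
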