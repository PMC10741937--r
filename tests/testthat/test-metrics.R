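test_that("overlap metrics reproduce analytic values", {
  g <- make_geom(c(10, 6, 6))
  a <- cube_mask(g, c(1, 1, 1), c(4, 4, 4))
  b <- cube_mask(g, c(3, 1, 1), c(6, 4, 4))   # shifted +2 voxels along x
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  disjoint <- cube_mask(g, c(6, 1, 1), c(9, 4, 4))
  expect_equal(dice(a, disjoint), 0)
  expect_equal(jaccard(a, disjoint), 0)
})

test_that("surface distances reproduce analytic values under anisotropy", {
  gi <- make_geom(c(5, 3, 3))
  a <- mask_from_indices(gi, cbind(1, 1, 1))
  b <- mask_from_indices(gi, cbind(4, 1, 1))
  expect_equal(hausdorff_distance(a, b), 3.0)
  ga <- make_geom(c(5, 3, 3), c(0.5, 0.5, 3))
  aa <- mask_from_indices(ga, cbind(1, 1, 1))
  ba <- mask_from_indices(ga, cbind(4, 1, 1))
  expect_equal(hausdorff_distance(aa, ba), 1.5)
  expect_equal(hausdorff_distance(a, a), 0)
  # A = {x=0}, B = {x=1, x=2}: directed means 1 and 1.5, average 1.25
  a2 <- mask_from_indices(gi, cbind(1, 2, 2))
  b2 <- mask_from_indices(gi, rbind(c(2, 2, 2), c(3, 2, 2)))
  expect_equal(mean_distance_to_agreement(a2, b2), 1.25)
  expect_equal(mean_distance_to_agreement(a2, a2), 0)
})

test_that("distance-transform metrics match the brute-force oracle", {
  set.seed(101)
  for (i in 1:40) {
    g <- make_geom(c(sample(5:12, 1), sample(5:12, 1), sample(4:8, 1)),
                   runif(3, 0.3, 3.5))
    a <- random_mask(g, runif(1, 0.05, 0.4))
    b <- random_mask(g, runif(1, 0.05, 0.4))
    if (!any(a$voxels) || !any(b$voxels)) next
    expect_equal(hausdorff_distance(a, b), brute_hausdorff(a, b),
                 tolerance = 1e-12)
    expect_equal(mean_distance_to_agreement(a, b), brute_mda(a, b),
                 tolerance = 1e-12)
  }
})

test_that("metrics are symmetric and satisfy their identities", {
  set.seed(7)
  for (i in 1:10) {
    g <- make_geom(c(10, 10, 6), runif(3, 0.4, 3))
    a <- random_mask(g, 0.25)
    b <- random_mask(g, 0.25)
    if (!any(a$voxels) || !any(b$voxels)) next
    d <- dice(a, b)
    expect_equal(dice(b, a), d)
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_equal(jaccard(a, b), d / (2 - d), tolerance = 1e-12)
    hd <- hausdorff_distance(a, b)
    mda <- mean_distance_to_agreement(a, b)
    expect_equal(hausdorff_distance(b, a), hd)
    expect_equal(mean_distance_to_agreement(b, a), mda)
    expect_lte(mda, hd)
    expect_lte(mean_distance_to_agreement(a, b, pooled = TRUE), hd)
  }
})

test_that("distances scale with spacing while overlaps do not", {
  set.seed(13)
  g1 <- make_geom(c(10, 10, 6), c(0.6, 0.9, 2))
  a1 <- random_mask(g1, 0.2); b1 <- random_mask(g1, 0.2)
  g2 <- make_geom(c(10, 10, 6), c(0.6, 0.9, 2) * 2.5)
  a2 <- binary_mask(a1$voxels, g2); b2 <- binary_mask(b1$voxels, g2)
  expect_equal(dice(a2, b2), dice(a1, b1))
  expect_equal(jaccard(a2, b2), jaccard(a1, b1))
  expect_equal(hausdorff_distance(a2, b2), 2.5 * hausdorff_distance(a1, b1))
  expect_equal(mean_distance_to_agreement(a2, b2),
               2.5 * mean_distance_to_agreement(a1, b1))
})

test_that("empty-mask conventions hold", {
  g <- make_geom(c(6, 6, 6))
  empty <- binary_mask(array(FALSE, g$shape), g)
  full <- cube_mask(g, c(2, 2, 2), c(4, 4, 4))
  expect_error(dice(empty, empty), class = "segvar_error_undefined_metric")
  expect_error(compare_masks(empty, empty),
               class = "segvar_error_undefined_metric")
  expect_error(hausdorff_distance(empty, full),
               class = "segvar_error_undefined_metric")
  expect_error(mean_distance_to_agreement(full, empty),
               class = "segvar_error_undefined_metric")
  res <- compare_masks(empty, full)
  expect_equal(res$dsc, 0)
  expect_equal(res$jaccard, 0)
  expect_true(is.na(res$hd_mm))
  expect_true(is.na(res$mda_mm))
  expect_equal(res$vol_a_ml, 0)
})

test_that("compare_masks bundles all metrics consistently", {
  g <- make_geom(c(10, 6, 6))
  a <- cube_mask(g, c(1, 1, 1), c(4, 4, 4))
  b <- cube_mask(g, c(3, 1, 1), c(6, 4, 4))
  res <- compare_masks(a, b)
  expect_equal(res$dsc, 0.5)
  expect_equal(res$jaccard, 1 / 3)
  expect_equal(res$hd_mm, hausdorff_distance(a, b))
  expect_equal(res$mda_mm, mean_distance_to_agreement(a, b))
  expect_equal(res$vol_a_ml, 0.064)
  expect_equal(res$vol_b_ml, 0.064)
  same <- compare_masks(a, a)
  expect_equal(unlist(same[c("dsc", "jaccard", "hd_mm", "mda_mm")]),
               c(dsc = 1, jaccard = 1, hd_mm = 0, mda_mm = 0))
  expect_error(compare_masks(a, random_mask(make_geom(c(9, 6, 6)), 0.2)),
               class = "segvar_error_geometry")
})
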