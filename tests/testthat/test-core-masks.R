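test_that("geometry validation and compatibility behave as specified", {
  g <- image_geometry(c(8, 8, 8), c(0.5, 0.5, 3))
  expect_s3_class(g, "image_geometry")
  expect_error(image_geometry(c(0, 8, 8), c(1, 1, 1)),
               class = "segvar_error_geometry")
  expect_error(image_geometry(c(8, 8, 8), c(1, -1, 1)),
               class = "segvar_error_geometry")
  g2 <- image_geometry(c(8, 8, 8), c(0.5, 0.5, 3), origin = c(5e-7, 0, 0))
  expect_true(geometry_compatible(g, g2))
  g3 <- image_geometry(c(8, 8, 8), c(0.5, 0.5, 3), origin = c(2e-6, 0, 0))
  expect_false(geometry_compatible(g, g3))
  expect_false(geometry_compatible(g, image_geometry(c(8, 8, 9), c(0.5, 0.5, 3))))
})

test_that("mask volume converts voxel counts through spacing", {
  g <- make_geom(c(10, 10, 10), c(1, 1, 1))
  expect_equal(mask_volume_ml(binary_mask(array(TRUE, c(10, 10, 10)), g)), 1)
  g2 <- make_geom(c(8, 8, 8), c(0.5, 0.5, 3))
  m <- cube_mask(g2, c(1, 1, 1), c(4, 4, 4))   # 64 voxels of 0.75 mm^3
  expect_equal(mask_volume_ml(m), 0.048)
  expect_equal(mask_volume_ml(binary_mask(array(FALSE, c(8, 8, 8)), g2)), 0)
})

test_that("mask volume is additive over disjoint masks", {
  g <- make_geom(c(12, 8, 6), c(0.7, 1.1, 2.3))
  set.seed(5)
  a <- random_mask(g, 0.2)
  b <- binary_mask(!a$voxels & (array(runif(prod(g$shape)), g$shape) < 0.3), g)
  expect_equal(mask_volume_ml(union_masks(list(a, b))),
               mask_volume_ml(a) + mask_volume_ml(b))
})

test_that("boundary extraction follows 6-connectivity with border rule", {
  g <- make_geom(c(6, 6, 6))
  single <- mask_from_indices(g, cbind(3, 3, 3))
  expect_identical(boundary_extract(single)$voxels, single$voxels)
  cube <- cube_mask(g, c(2, 2, 2), c(5, 5, 5))
  expect_equal(sum(boundary_extract(cube)$voxels), 56)  # 64 - 2^3 interior
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_equal(sum(boundary_extract(empty)$voxels), 0)
  # mask voxels on the array border are boundary
  full <- binary_mask(array(TRUE, c(3, 3, 3)), make_geom(c(3, 3, 3)))
  expect_equal(sum(boundary_extract(full)$voxels), 26)
})

test_that("boundary is a subset of the mask and stable for thin masks", {
  set.seed(11)
  for (i in 1:5) {
    g <- make_geom(c(9, 9, 6), runif(3, 0.4, 3))
    m <- random_mask(g, 0.25)
    b <- boundary_extract(m)
    expect_true(all(!b$voxels | m$voxels))
    expect_identical(boundary_extract(b)$voxels, b$voxels)
  }
})

test_that("NIfTI round-trip preserves voxels, spacing and origin", {
  dir <- withr::local_tempdir()
  g <- image_geometry(c(16, 16, 16), c(0.5, 0.5, 3.0),
                      origin = c(-12.25, 3.5, 7.125))
  set.seed(3)
  m <- random_mask(g, 0.3)
  p <- file.path(dir, "m.nii.gz")
  save_mask_volume(m, p)
  m2 <- load_mask_volume(p)
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$geometry$spacing, g$spacing, tolerance = 1e-9)
  expect_true(all(abs(m2$geometry$origin - g$origin) < 1e-6))

  zero <- binary_mask(array(FALSE, c(8, 8, 8)), make_geom(c(8, 8, 8)))
  pz <- file.path(dir, "zero.nii")
  save_mask_volume(zero, pz)
  expect_equal(sum(load_mask_volume(pz)$voxels), 0)

  m64 <- cube_mask(make_geom(c(8, 8, 8)), c(1, 1, 1), c(4, 4, 4))
  p64 <- file.path(dir, "c.nii.gz")
  save_mask_volume(m64, p64)
  expect_equal(sum(load_mask_volume(p64)$voxels), 64)
})

test_that("loading rejects missing files and geometry mismatches", {
  dir <- withr::local_tempdir()
  expect_error(load_mask_volume(file.path(dir, "absent.nii.gz")),
               class = "segvar_error_missing_file")
  m <- random_mask(make_geom(c(8, 8, 8)), 0.2)
  p <- file.path(dir, "m.nii.gz")
  save_mask_volume(m, p)
  expect_error(load_mask_volume(p, image_geometry(c(8, 8, 9), c(1, 1, 1))),
               class = "segvar_error_geometry")
  expect_s3_class(load_mask_volume(p, m$geometry), "binary_mask")
})

test_that("case metadata is validated on load", {
  dir <- withr::local_tempdir()
  meta <- data.frame(case_id = c("a", "b"), age = c(60, 70),
                     pirads = c(4, 5), psa = c(8.1, 12), isup = c(2, 4))
  p <- file.path(dir, "meta.csv")
  write.csv(meta, p, row.names = FALSE)
  expect_equal(nrow(load_case_meta(p)), 2)
  bad <- meta; bad$pirads[1] <- 2
  write.csv(bad, p, row.names = FALSE)
  expect_error(load_case_meta(p), class = "segvar_error_metadata")
  bad <- meta; bad$psa[2] <- 0
  write.csv(bad, p, row.names = FALSE)
  expect_error(load_case_meta(p), class = "segvar_error_metadata")
})
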