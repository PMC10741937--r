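# Shared fixtures: small geometries, hand-built masks, and the brute-force
# surface-distance oracle the distance-transform implementation is checked
# against.

make_geom <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1)) {
  image_geometry(shape, spacing)
}

mask_from_indices <- function(geom, idx) {
  v <- array(FALSE, geom$shape)
  v[idx] <- TRUE
  binary_mask(v, geom)
}

cube_mask <- function(geom, from, to) {
  v <- array(FALSE, geom$shape)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(v, geom)
}

random_mask <- function(geom, p = 0.2) {
  binary_mask(array(runif(prod(geom$shape)) < p, geom$shape), geom)
}

# Boundary voxel centres in mm, using the package's boundary definition.
boundary_points_mm <- function(mask) {
  b <- boundary_extract(mask)$voxels
  idx <- which(b, arr.ind = TRUE)
  t(t(idx - 1) * mask$geometry$spacing)
}

# Exhaustive all-pairs directed distances between boundary point sets.
brute_surface_distances <- function(a, b) {
  pa <- boundary_points_mm(a)
  pb <- boundary_points_mm(b)
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
              outer(pa[, 2], pb[, 2], "-")^2 +
              outer(pa[, 3], pb[, 3], "-")^2)
  list(a_to_b = apply(d, 1, min), b_to_a = apply(d, 2, min))
}

brute_hausdorff <- function(a, b) {
  d <- brute_surface_distances(a, b)
  max(max(d$a_to_b), max(d$b_to_a))
}

brute_mda <- function(a, b) {
  d <- brute_surface_distances(a, b)
  (mean(d$a_to_b) + mean(d$b_to_a)) / 2
}

# A compact simulation config for unit tests: coarse 48x48x12 grid at
# (1, 1, 3) mm keeps single tests in seconds while exercising the same code
# paths as the study-scale default.
# Agreement targets are milder than the study defaults because the coarse
# grid cannot reach very low DSC within the amplitude bound.
tiny_config <- function(n_cases = 4, seed = 1,
                        pirads_counts = c(`3` = 1, `4` = 1, `5` = 2), ...) {
  simulation_config(
    n_cases = n_cases, seed = seed,
    geometry = image_geometry(c(48, 48, 16), c(1, 1, 3)),
    gland_volume_ml = c(mean = 24, sd = 3),
    pirads_counts = pirads_counts,
    per_sequence_target_dsc = c(T2 = 0.56, ADC = 0.55, T2ADC = 0.59,
                                B2000 = 0.57, T2ADCB2000 = 0.59, DCE = 0.47,
                                T2ADCDCE = 0.60, ALL = 0.58),
    pirads5_dsc_boost = 0.05,
    calibration = list(n_mc = 30, tol = 0.01, max_amplitude_mm = 8),
    ...)
}
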