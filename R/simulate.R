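# ---------------------------------------------------------------------------
# Synthetic multi-reader cohort: ground-truth anatomy as implicit shapes,
# reader variability as a similarity-transform jitter plus a correlated
# Gaussian random field added to the truth's signed-distance function, with
# per-sequence field amplitudes calibrated against target mean pairwise DSC.
# ---------------------------------------------------------------------------

# Deterministic 31-bit sub-seed derivation so every case/reader/sequence has
# its own reproducible RNG stream.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in c(...)) x <- (x * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(x)
}

#' Reader noise model
#'
#' The variability mechanism applied to a ground-truth shape: a per-reader
#' random translation (mm) and isotropic scale jitter shared across all of
#' that reader's structures, plus a spatially correlated Gaussian random
#' field added to the truth signed-distance function and thresholded at
#' zero. The field amplitude (mm) is per-sequence and is what
#' [calibrate_noise()] tunes.
#'
#' @param translation_sd_mm standard deviation of each translation component.
#' @param scale_sd standard deviation of log isotropic scale.
#' @param boundary_correlation_mm Gaussian correlation length of the field.
#' @param field_share fraction of field variance shared across one reader's
#'   sequences (drives inter-sequence correlation of that reader's
#'   contours), in \[0, 1\].
#' @return an object of class `reader_noise_model`.
#' @export
reader_noise_model <- function(translation_sd_mm = 0.5, scale_sd = 0.02,
                               boundary_correlation_mm = 5, field_share = 0.35) {
  stopifnot(translation_sd_mm >= 0, scale_sd >= 0,
            boundary_correlation_mm >= 0, field_share >= 0, field_share <= 1)
  structure(list(translation_sd_mm = translation_sd_mm, scale_sd = scale_sd,
                 boundary_correlation_mm = boundary_correlation_mm,
                 field_share = field_share),
            class = "reader_noise_model")
}

#' Configuration of the synthetic cohort
#'
#' Defaults encode the cohort the pipeline is designed for: 64 cases, 3
#' readers, PI-RADS counts 7/12/45, gland volumes around 42 mL, lesion
#' volumes log-normal with mean 3 mL, per-sequence target mean pairwise DSC
#' of 0.51 (T2), 0.50 (ADC), 0.54 (T2ADC), 0.52 (B2000), 0.54 (T2ADCB2000),
#' 0.35 (DCE), 0.55 (T2ADCDCE), 0.53 (ALL), gland DSC 0.90 and TZ 0.77, on
#' a 96x96x24 grid at (0.5, 0.5, 3.0) mm.
#'
#' @param n_cases number of cases.
#' @param seed integer seed fixing the entire cohort.
#' @param geometry an [image_geometry()].
#' @param gland_volume_ml `c(mean, sd)` of the normal gland volume draw.
#' @param lesion_volume_ml `c(meanlog, sdlog)` of the log-normal lesion
#'   volume draw.
#' @param pirads_counts named or ordered counts for PI-RADS 3/4/5, summing
#'   to `n_cases`.
#' @param per_sequence_target_dsc named vector of target mean pairwise DSC
#'   for the eight delineated labels.
#' @param gland_target_dsc,tz_target_dsc targets for prostate and TZ (the
#'   peripheral zone is derived as gland minus TZ, so its agreement is
#'   emergent).
#' @param pirads5_dsc_boost additive DSC separation between PI-RADS 5 and
#'   other cases, applied mean-preservingly to every boosted sequence.
#' @param boost_sequences labels the boost applies to (default: all
#'   delineated labels except DCE).
#' @param noise a [reader_noise_model()].
#' @param pirads_rank_jitter sdlog of the lognormal jitter applied to lesion
#'   volumes before rank-based PI-RADS assignment (0 = deterministic
#'   quantile assignment).
#' @param lesion_shape_sd coefficient sd of the degree-2 spherical-harmonic
#'   lesion surface perturbation.
#' @param amplitude_volume_exponent exponent `e` of the per-case amplitude
#'   multiplier `(lesion volume / reference volume)^e`, partially scaling
#'   the boundary-noise band with lesion size. 0 gives a fixed amplitude
#'   whose strong surface-to-volume effect lets volume dominate the grade in
#'   multivariate analysis; 1/3 makes expected DSC fully size-invariant
#'   within a grade group and starves the marginal volume correlation. The
#'   default 0.2 keeps a moderate direct volume effect while the grade
#'   retains independent signal.
#' @param calibration list: `n_mc` Monte-Carlo reader pairs, `tol` DSC
#'   tolerance, `max_amplitude_mm` upper amplitude bound.
#' @param n_readers number of readers.
#' @param include_dce whether [generate_cohort()] also simulates a DCE
#'   series per case.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cases = 64, seed = 1,
    geometry = image_geometry(c(96, 96, 24), c(0.5, 0.5, 3.0)),
    gland_volume_ml = c(mean = 42, sd = 8),
    lesion_volume_ml = c(meanlog = log(3.0) - 0.45^2 / 2, sdlog = 0.45),
    pirads_counts = c(`3` = 7, `4` = 12, `5` = 45),
    per_sequence_target_dsc = c(T2 = 0.51, ADC = 0.50, T2ADC = 0.54,
                                B2000 = 0.52, T2ADCB2000 = 0.54, DCE = 0.35,
                                T2ADCDCE = 0.55, ALL = 0.53),
    gland_target_dsc = 0.90, tz_target_dsc = 0.77,
    pirads5_dsc_boost = 0.16,
    boost_sequences = setdiff(delineated_sequence_labels(), "DCE"),
    noise = reader_noise_model(),
    pirads_rank_jitter = 0.7,
    lesion_shape_sd = 0.08,
    amplitude_volume_exponent = 0.2,
    calibration = list(n_mc = 80, tol = 0.015, max_amplitude_mm = 8),
    n_readers = 3,
    include_dce = FALSE) {
  if (sum(pirads_counts) != n_cases)
    abort_segvar("pirads_counts must sum to n_cases", "segvar_error_config")
  targets <- per_sequence_target_dsc
  if (!setequal(names(targets), delineated_sequence_labels()))
    abort_segvar("per_sequence_target_dsc must name the 8 delineated labels",
                 "segvar_error_config")
  if (any(targets <= 0 | targets > 1) || gland_target_dsc <= 0 ||
      gland_target_dsc > 1)
    abort_segvar("DSC targets must lie in (0, 1]", "segvar_error_config")
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    geometry = geometry, gland_volume_ml = gland_volume_ml,
    lesion_volume_ml = lesion_volume_ml,
    pirads_counts = pirads_counts,
    per_sequence_target_dsc = targets[delineated_sequence_labels()],
    gland_target_dsc = gland_target_dsc, tz_target_dsc = tz_target_dsc,
    pirads5_dsc_boost = pirads5_dsc_boost, boost_sequences = boost_sequences,
    noise = noise, pirads_rank_jitter = pirads_rank_jitter,
    lesion_shape_sd = lesion_shape_sd,
    amplitude_volume_exponent = amplitude_volume_exponent,
    calibration = calibration,
    n_readers = as.integer(n_readers), include_dce = include_dce),
    class = "simulation_config")
}

# --- random fields ---------------------------------------------------------

gaussian_kernel <- function(sigma) {
  if (sigma <= 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Unit-variance Gaussian random field with the configured correlation
# length, honoring anisotropic spacing. White noise is drawn and smoothed on
# a coarser grid (node spacing ~ correlation/2.5, never coarser than needed
# to resolve the correlation) and trilinearly upsampled: the field is
# band-limited at the correlation length, so the coarse representation
# loses almost nothing while cutting the cost several-fold. Uses the
# current RNG stream.
smooth_unit_field <- function(geometry, correlation_mm) {
  sh <- geometry$shape
  sp <- geometry$spacing
  if (correlation_mm <= 1e-8) {
    f <- rnorm(prod(sh))
    dim(f) <- sh
    return(f)
  }
  target <- correlation_mm / 2.5
  csp <- pmax(sp, pmin(target, sp * pmax(1, floor(target / sp))))
  cdim <- as.integer(pmin(sh, ceiling((sh - 1) * sp / csp) + 1))
  noise <- rnorm(prod(cdim))
  sig <- correlation_mm / csp
  kx <- gaussian_kernel(sig[1]); ky <- gaussian_kernel(sig[2])
  kz <- gaussian_kernel(sig[3])
  f <- .convolve_sep3(noise, cdim, kx, ky, kz)
  f <- f / sqrt(sum(kx^2) * sum(ky^2) * sum(kz^2))
  if (identical(cdim, sh) && all(abs(csp - sp) < 1e-12)) {
    dim(f) <- sh
    return(f)
  }
  .resample_trilinear(f, cdim, csp, sh, sp)
}

# --- signed distance and thresholding --------------------------------------

# Signed distance (mm) between voxel centers: negative inside, positive
# outside.
sdf_from_voxels <- function(voxels, spacing) {
  dims <- as.integer(dim(voxels))
  d_out <- .edt_mm(as.logical(voxels), dims, spacing)
  d_in <- .edt_mm(!voxels, dims, spacing)
  phi <- d_out - d_in
  dim(phi) <- dims
  phi
}

keep_largest_component <- function(voxels) {
  if (!any(voxels)) return(voxels)
  lab <- .label_components6(as.logical(voxels), as.integer(dim(voxels)))
  tab <- tabulate(lab[lab > 0L])
  out <- lab == which.max(tab)
  dim(out) <- dim(voxels)
  out
}

# --- implicit shapes -------------------------------------------------------

superellipsoid_volume_factor <- function(n) {
  8 * gamma(1 + 1 / n)^3 / gamma(1 + 3 / n)
}

# Axis coordinate vectors of voxel centers in the grid-internal mm frame.
grid_axes_mm <- function(geometry) {
  lapply(1:3, function(i) (seq_len(geometry$shape[i]) - 1) * geometry$spacing[i])
}

rasterize_superellipsoid <- function(geometry, center, semi, n_exp) {
  ax <- grid_axes_mm(geometry)
  ex <- abs((ax[[1]] - center[1]) / semi[1])^n_exp
  ey <- abs((ax[[2]] - center[2]) / semi[2])^n_exp
  ez <- abs((ax[[3]] - center[3]) / semi[3])^n_exp
  v <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  dim(v) <- geometry$shape
  v
}

# Ellipsoid with a degree-2 real-spherical-harmonic radial perturbation.
rasterize_blob <- function(geometry, center, semi, harm_coef) {
  sh <- geometry$shape
  ax <- grid_axes_mm(geometry)
  vx <- array(rep((ax[[1]] - center[1]) / semi[1], times = sh[2] * sh[3]), sh)
  vy <- array(rep(rep((ax[[2]] - center[2]) / semi[2], each = sh[1]),
                  times = sh[3]), sh)
  vz <- array(rep((ax[[3]] - center[3]) / semi[3], each = sh[1] * sh[2]), sh)
  rho <- sqrt(vx^2 + vy^2 + vz^2)
  safe <- pmax(rho, 1e-9)
  ux <- vx / safe; uy <- vy / safe; uz <- vz / safe
  pert <- harm_coef[1] * (ux * uy) + harm_coef[2] * (uy * uz) +
    harm_coef[3] * (ux * uz) + harm_coef[4] * (ux^2 - uy^2) +
    harm_coef[5] * (3 * uz^2 - 1) / 2
  rho <= 1 + pert
}

#' Sample the ground-truth gland, transition and peripheral zones
#'
#' The gland is a superellipsoid with volume drawn from the configured
#' normal distribution; the transition zone is a concentric scaled copy and
#' the peripheral zone the set difference. Glands that would not fit on the
#' grid (with a 2 mm margin) are redrawn a bounded number of times, then the
#' volume is truncated to the largest feasible value with a warning.
#'
#' @param config a [simulation_config()].
#' @param case_seed integer seed for this case.
#' @return list with `gland`, `tz`, `pz` (`binary_mask`), `center` (mm),
#'   `gland_volume_ml` (the sampled target).
#' @export
generate_gland <- function(config, case_seed) {
  g <- config$geometry
  set.seed(derive_seed(case_seed, 11))
  fov <- (g$shape - 1) * g$spacing
  center <- fov / 2
  margin <- 2
  vol <- NA
  semi <- NULL
  n_exp <- runif(1, 2.2, 3.0)
  bf <- superellipsoid_volume_factor(n_exp)
  for (try in 1:20) {
    vol <- rnorm(1, config$gland_volume_ml["mean"], config$gland_volume_ml["sd"])
    vol <- max(vol, 12)
    ratios <- exp(rnorm(3, 0, c(0.06, 0.06, 0.10)))
    ratios <- ratios / prod(ratios)^(1 / 3)
    r0 <- (vol * 1000 / bf)^(1 / 3)
    semi <- r0 * ratios
    if (all(semi + margin <= fov / 2)) break
    if (try == 20) {
      warn_segvar("gland exceeds grid after 20 retries; truncating volume",
                  "segvar_warning_gland_truncated")
      shrink <- min((fov / 2 - margin) / semi)
      semi <- semi * shrink
    }
  }
  gl <- rasterize_superellipsoid(g, center, semi, n_exp)
  frac <- min(max(0.35 * exp(rnorm(1, 0, 0.15)), 0.2), 0.55)
  tz <- rasterize_superellipsoid(g, center, semi * frac^(1 / 3), n_exp) & gl
  pz <- gl & !tz
  list(gland = binary_mask(gl, g), tz = binary_mask(tz, g),
       pz = binary_mask(pz, g), center = center, semi = semi, n_exp = n_exp,
       gland_volume_ml = vol)
}

# Ellipsoid semi-axes for a target volume with mild random anisotropy plus
# harmonic surface coefficients; shared by cohort lesions and the
# calibration shape family.
sample_lesion_shape_params <- function(volume_ml, shape_sd) {
  ratios <- exp(rnorm(3, 0, 0.15))
  ratios <- ratios / prod(ratios)^(1 / 3)
  r0 <- (volume_ml * 1000 * 3 / (4 * pi))^(1 / 3)
  list(semi = r0 * ratios, harm = rnorm(5, 0, shape_sd))
}

#' Sample a ground-truth lesion inside the gland
#'
#' An ellipsoid with a low-order spherical-harmonic surface perturbation,
#' placed in the peripheral (70%) or transition (30%) zone at a voxel with
#' enough interior depth, then clipped to the gland. The volume is drawn
#' log-normally unless given; if `pirads` is supplied (and no volume), the
#' draw is restricted to the quantile band matching the positive
#' volume/PI-RADS association (3: lower 30%, 4: 20-60%, 5: upper 60%).
#'
#' @param config a [simulation_config()].
#' @param case_seed integer seed.
#' @param gland result of [generate_gland()].
#' @param pirads optional PI-RADS category in \{3,4,5\}.
#' @param volume_ml optional explicit target volume (overrides the draw).
#' @return list with `lesion` (`binary_mask`), `center`, `target_volume_ml`.
#' @export
generate_lesion <- function(config, case_seed, gland, pirads = NULL,
                            volume_ml = NULL) {
  g <- config$geometry
  set.seed(derive_seed(case_seed, 23))
  lv <- config$lesion_volume_ml
  if (is.null(volume_ml)) {
    q <- if (is.null(pirads)) runif(1)
         else switch(as.character(pirads),
                     "3" = runif(1, 0, 0.30),
                     "4" = runif(1, 0.20, 0.60),
                     "5" = runif(1, 0.40, 1))
    volume_ml <- stats::qlnorm(q, lv["meanlog"], lv["sdlog"])
  }
  shape <- sample_lesion_shape_params(volume_ml, config$lesion_shape_sd)
  rmax <- max(shape$semi) * (1 + 3 * config$lesion_shape_sd)

  depth <- .edt_mm(!gland$gland$voxels, g$shape, g$spacing)
  zone_vox <- if (runif(1) < 0.7) gland$pz$voxels else gland$tz$voxels
  cand <- which(zone_vox & depth >= 0.5 * rmax)
  if (length(cand) == 0) cand <- which(zone_vox & depth >= 0.8 * max(depth[zone_vox]))
  if (length(cand) == 0)
    abort_segvar("lesion placement failed: no candidate voxels",
                 "segvar_error_placement")
  pick <- cand[sample.int(length(cand), 1)]
  idx <- arrayInd(pick, g$shape)
  center <- (as.numeric(idx) - 1) * g$spacing
  lesion <- rasterize_blob(g, center, shape$semi, shape$harm) & gland$gland$voxels
  list(lesion = binary_mask(lesion, g), center = center,
       target_volume_ml = unname(volume_ml))
}

# --- reader delineation ----------------------------------------------------

sample_reader_affine <- function(noise) {
  list(trans = rnorm(3, 0, noise$translation_sd_mm),
       scale = exp(rnorm(1, 0, noise$scale_sd)))
}

# Every reader draw has its own derived seed so the calibration stage can
# reproduce exactly the realizations the simulator will use (common random
# numbers across amplitude search and cohort generation).
noise_stream_index <- function(lab) {
  match(lab, c(delineated_sequence_labels(), "gland", "tz"))
}

reader_affine_and_shared <- function(case_seed, r, geometry, noise) {
  set.seed(derive_seed(case_seed, 41, r))
  list(affine = sample_reader_affine(noise),
       shared = smooth_unit_field(geometry, noise$boundary_correlation_mm))
}

# Per-structure field: the reader's shared component (driving inter-sequence
# correlation of one reader's contours) mixed with a structure-specific one.
reader_structure_field <- function(case_seed, r, lab, geometry, noise,
                                   shared, attempt = 1) {
  set.seed(derive_seed(case_seed, if (attempt == 1) 43 else 44, r,
                       noise_stream_index(lab)))
  own <- smooth_unit_field(geometry, noise$boundary_correlation_mm)
  w <- noise$field_share
  sqrt(w) * shared + sqrt(1 - w) * own
}

# Core delineation: similarity-transformed SDF plus amplitude * field,
# thresholded at zero; keeps the largest 6-connected component.
delineate <- function(sdf, geometry, center, affine, field, amplitude) {
  phi <- .sdf_similarity_sample(sdf, geometry$shape,
                                geometry$spacing, center,
                                affine$trans, affine$scale)
  v <- (phi + amplitude * field) < 0
  dim(v) <- geometry$shape
  keep_largest_component(v)
}

#' Simulate one reader's delineation of a truth shape
#'
#' Applies a reader-specific random translation and isotropic scale jitter
#' to the truth signed-distance function, adds a correlated Gaussian field
#' scaled by `amplitude`, thresholds at zero and keeps the largest
#' 6-connected component. With zero translation/scale jitter and zero
#' amplitude the rasterized truth is returned exactly. An empty result is
#' regenerated once with a fresh field, then flagged with a warning.
#'
#' @param truth_sdf 3D signed-distance array (mm) of the truth shape, e.g.
#'   from a rasterized mask.
#' @param geometry the grid geometry.
#' @param noise a [reader_noise_model()].
#' @param amplitude field amplitude in mm (e.g. from [calibrate_noise()]).
#' @param seed reader seed.
#' @param center mm centre the scale jitter pivots about (defaults to the
#'   grid centre).
#' @return a `binary_mask`.
#' @export
simulate_reader_delineation <- function(truth_sdf, geometry, noise, amplitude,
                                        seed, center = NULL) {
  if (is.null(center)) center <- (geometry$shape - 1) * geometry$spacing / 2
  set.seed(seed)
  affine <- sample_reader_affine(noise)
  field <- smooth_unit_field(geometry, noise$boundary_correlation_mm)
  v <- delineate(truth_sdf, geometry, center, affine, field, amplitude)
  if (!any(v)) {
    field <- smooth_unit_field(geometry, noise$boundary_correlation_mm)
    v <- delineate(truth_sdf, geometry, center, affine, field, amplitude)
    if (!any(v))
      warn_segvar("reader delineation empty after regeneration",
                  "segvar_warning_empty_delineation")
  }
  binary_mask(v, geometry)
}

# --- amplitude calibration -------------------------------------------------

# Encode, per voxel, the half-line of field amplitudes at which the voxel is
# inside (phi + a * f < 0): +Inf always, -Inf never, t > 0 member for a < t,
# t <= 0 member for a > -t.
encode_membership <- function(phi, f) {
  t <- numeric(length(phi))
  pos <- f > 0; neg <- f < 0; zero <- !pos & !neg
  inside <- phi < 0
  t[pos & inside] <- -phi[pos & inside] / f[pos & inside]
  t[pos & !inside] <- -Inf
  t[neg & inside] <- Inf
  t[neg & !inside] <- -(phi[neg & !inside] / (-f[neg & !inside]))
  t[zero] <- ifelse(inside[zero], Inf, -Inf)
  t
}

decode_membership <- function(t, a) {
  (t == Inf) | (t > 0 & a < t) | (is.finite(t) & t <= 0 & a > -t)
}

# Root-finder over a fixed set of amplitude-encoded reader pairs: the same
# realizations are re-thresholded at every candidate amplitude (common
# random numbers), so the DSC(amplitude) curve is smooth and monotone. Each
# rep may carry a fixed amplitude multiplier `m` (per-case size scaling);
# the solved amplitude is the common base value.
amplitude_solver <- function(reps, dims, max_amplitude = 8, tol = 0.005) {
  rep_mult <- vapply(reps, function(p) {
    if (!is.null(p$m)) p$m else 1
  }, 0)
  # Mean pairwise DSC at base amplitude `a`, with the simulator's
  # largest-component post-processing (the quantity being calibrated).
  mean_dsc <- function(a) {
    vals <- vapply(seq_along(reps), function(i) {
      p <- reps[[i]]
      cnt <- .cc_tenc_counts(p[[1]], p[[2]], a * rep_mult[i], dims)
      if (cnt[1] + cnt[2] == 0) return(NA_real_)
      2 * cnt[3] / (cnt[1] + cnt[2])
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  # Cheaper variant without the component filter, only used to bracket.
  mean_dsc_fast <- function(a) {
    vals <- vapply(seq_along(reps), function(i) {
      p <- reps[[i]]
      cnt <- .tenc_counts(p[[1]], p[[2]], a * rep_mult[i])
      if (cnt[1] + cnt[2] == 0) return(NA_real_)
      2 * cnt[3] / (cnt[1] + cnt[2])
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  curve <- NULL
  bracket_from_curve <- function(target) {
    if (is.null(curve)) {
      amps <- c(0, exp(seq(log(0.05), log(max_amplitude), length.out = 23)))
      curve <<- data.frame(a = amps, d = vapply(amps, mean_dsc_fast, 0))
    }
    # fast curve underestimates DSC slightly (stray specks inflate the
    # denominators), so widen the bracket by one grid step on each side
    below <- which(curve$d < target)
    hi_i <- if (length(below)) min(below) else nrow(curve)
    c(curve$a[max(1, hi_i - 2)], curve$a[min(nrow(curve), hi_i + 1)])
  }
  d0 <- NULL
  dhi <- NULL
  amplitude_for <- function(target) {
    if (target >= 1 - 1e-12) return(0)
    if (is.null(d0)) d0 <<- mean_dsc(0)
    if (target > d0)
      abort_segvar(sprintf(
        "target DSC %.3f unreachable: affine jitter alone gives %.3f (bracket [0, %.1f])",
        target, d0, max_amplitude), "segvar_error_unreachable_target")
    if (is.null(dhi)) dhi <<- mean_dsc(max_amplitude)
    if (dhi > target)
      abort_segvar(sprintf(
        "target DSC %.3f unreachable within amplitude bounds [0, %.1f] (DSC at bound %.3f)",
        target, max_amplitude, dhi), "segvar_error_unreachable_target")
    br <- bracket_from_curve(target)
    lo <- br[1]; hi <- br[2]
    dlo <- mean_dsc(lo)
    if (dlo < target) { lo <- 0; dlo <- d0 }
    if (mean_dsc(hi) > target) hi <- max_amplitude
    for (iter in 1:20) {
      mid <- (lo + hi) / 2
      dm <- mean_dsc(mid)
      if (abs(dm - target) < tol / 2 || (hi - lo) < 1e-3) return(mid)
      if (dm > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  list(mean_dsc = mean_dsc, amplitude_for = amplitude_for)
}

# Precompute n_mc Monte-Carlo reader pairs over a truth-shape family so the
# mean pairwise DSC can be evaluated at any amplitude.
make_dsc_calibrator <- function(shape_sampler, geometry, noise, n_mc, seed,
                                max_amplitude = 8, tol = 0.005) {
  reps <- vector("list", n_mc)
  for (r in seq_len(n_mc)) {
    set.seed(derive_seed(seed, 101, r))
    shp <- shape_sampler()
    sdf <- sdf_from_voxels(shp$voxels, geometry$spacing)
    reps[[r]] <- lapply(1:2, function(k) {
      affine <- sample_reader_affine(noise)
      field <- smooth_unit_field(geometry, noise$boundary_correlation_mm)
      phi <- .sdf_similarity_sample(sdf, geometry$shape, geometry$spacing,
                                    shp$center, affine$trans, affine$scale)
      encode_membership(phi, field)
    })
  }
  amplitude_solver(reps, geometry$shape, max_amplitude, tol)
}

#' Calibrate the boundary-field amplitude for a target mean pairwise DSC
#'
#' Bisection on the field amplitude such that the mean pairwise DSC over
#' `n_mc` simulated reader pairs (each on a fresh shape drawn from the
#' truth-shape family) is within tolerance of the target. A target of 1
#' returns amplitude 0; targets above what the affine jitter alone permits,
#' or below what the amplitude bound permits, raise an error reporting the
#' bracket.
#'
#' @param target_dsc target mean pairwise DSC in (0, 1\].
#' @param shape_sampler zero-argument function returning
#'   `list(voxels = <logical 3D array>, center = <mm triple>)` drawn from
#'   the truth-shape family (uses the current RNG stream).
#' @param geometry grid geometry of the sampled shapes.
#' @param noise a [reader_noise_model()].
#' @param n_mc Monte-Carlo reader pairs.
#' @param seed RNG seed.
#' @param max_amplitude amplitude upper bound in mm.
#' @param tol DSC tolerance of the bisection.
#' @return amplitude in mm.
#' @export
calibrate_noise <- function(target_dsc, shape_sampler, geometry, noise,
                            n_mc = 80, seed = 1, max_amplitude = 8,
                            tol = 0.015) {
  if (target_dsc <= 0 || target_dsc > 1)
    abort_segvar("target_dsc must be in (0, 1]", "segvar_error_config")
  if (target_dsc >= 1 - 1e-12) return(0)
  cal <- make_dsc_calibrator(shape_sampler, geometry, noise, n_mc, seed,
                             max_amplitude, tol)
  cal$amplitude_for(target_dsc)
}

# Shape samplers for the calibration families (use current RNG stream).
lesion_shape_sampler <- function(config) {
  g <- config$geometry
  fov <- (g$shape - 1) * g$spacing
  lv <- config$lesion_volume_ml
  function() {
    vol <- rlnorm(1, lv["meanlog"], lv["sdlog"])
    shape <- sample_lesion_shape_params(vol, config$lesion_shape_sd)
    center <- fov / 2 + runif(3, -1, 1) * g$spacing
    list(voxels = rasterize_blob(g, center, shape$semi, shape$harm),
         center = center)
  }
}

gland_shape_sampler <- function(config, tz = FALSE) {
  function() {
    gl <- generate_gland(config, derive_seed(sample.int(2^31 - 1, 1), 7))
    m <- if (tz) gl$tz else gl$gland
    list(voxels = m$voxels, center = gl$center)
  }
}

# --- cohort ----------------------------------------------------------------

# Per-case lesion amplitude multiplier: scales the boundary-noise band with
# lesion linear size so expected DSC is approximately size-invariant.
case_amplitude_multiplier <- function(config, lesion_volume_ml) {
  e <- config$amplitude_volume_exponent
  if (is.null(e) || e == 0) return(1)
  vref <- exp(config$lesion_volume_ml[["meanlog"]] +
                config$lesion_volume_ml[["sdlog"]]^2 / 2)
  (pmax(lesion_volume_ml, 0.05) / vref)^e
}

# Ground-truth shapes of one case, as signed-distance fields (the only form
# the reader model needs; masks are recoverable as sdf < 0).
generate_truth <- function(config, case_seed, lesion_volume_ml) {
  sp <- config$geometry$spacing
  gl <- generate_gland(config, case_seed)
  les <- generate_lesion(config, case_seed, gl, volume_ml = lesion_volume_ml)
  list(sdf_gland = sdf_from_voxels(gl$gland$voxels, sp),
       sdf_tz = sdf_from_voxels(gl$tz$voxels, sp),
       sdf_lesion = sdf_from_voxels(les$lesion$voxels, sp),
       gland_center = gl$center, lesion_center = les$center,
       gland_volume_ml = mask_volume_ml(gl$gland),
       tz_volume_ml = mask_volume_ml(gl$tz),
       lesion_volume_ml = mask_volume_ml(les$lesion))
}

# Per-sequence, per-PI-RADS-group amplitudes, calibrated against the
# cohort's own truth shapes and the exact seeded reader realizations the
# simulator will use (full common random numbers): the root-finder then
# matches the realized per-sequence cohort mean DSC up to the bisection
# tolerance instead of up to Monte-Carlo error. The PI-RADS-5 boost is
# mean-preserving: group targets t + b*n_other/n and t - b*n5/n keep the
# cohort mean at t while separating the groups by b on boosted sequences.
calibrate_cohort_amplitudes <- function(config, meta, truths,
                                        progress = FALSE) {
  g <- config$geometry; dims <- g$shape; sp <- g$spacing
  noise <- config$noise
  n <- config$n_cases; R <- config$n_readers
  cal <- config$calibration
  pair_idx <- utils::combn(R, 2)

  ctx <- vector("list", n)
  phi_les <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- derive_seed(config$seed, 500, i)
    ctx[[i]] <- lapply(seq_len(R), function(r)
      reader_affine_and_shared(cs, r, g, noise))
    phi_les[[i]] <- lapply(seq_len(R), function(r)
      .sdf_similarity_sample(truths[[i]]$sdf_lesion, dims, sp,
                             truths[[i]]$lesion_center,
                             ctx[[i]][[r]]$affine$trans,
                             ctx[[i]][[r]]$affine$scale))
  }

  grp5 <- meta$pirads == 5L
  n5 <- sum(grp5); nother <- n - n5
  b <- config$pirads5_dsc_boost

  encode_label <- function(lab, phi) {
    tenc <- vector("list", n)
    for (i in seq_len(n)) {
      cs <- derive_seed(config$seed, 500, i)
      tenc[[i]] <- lapply(seq_len(R), function(r) {
        f <- reader_structure_field(cs, r, lab, g, noise,
                                    ctx[[i]][[r]]$shared)
        encode_membership(phi[[i]][[r]], f)
      })
    }
    tenc
  }
  mult <- vapply(truths, function(tr)
    case_amplitude_multiplier(config, tr$lesion_volume_ml), 0)
  pairs_for <- function(tenc, case_sel, use_mult = TRUE) {
    out <- list()
    for (i in which(case_sel))
      for (p in seq_len(ncol(pair_idx)))
        out[[length(out) + 1]] <- list(tenc[[i]][[pair_idx[1, p]]],
                                       tenc[[i]][[pair_idx[2, p]]],
                                       m = if (use_mult) mult[i] else 1)
    out
  }

  seq_amp <- list()
  for (lab in delineated_sequence_labels()) {
    tenc <- encode_label(lab, phi_les)
    t0 <- config$per_sequence_target_dsc[[lab]]
    boosted <- lab %in% config$boost_sequences && b > 0 && n5 > 0 && nother > 0
    t5 <- if (boosted) t0 + b * nother / n else t0
    to <- if (boosted) t0 - b * n5 / n else t0
    a5 <- if (n5 > 0)
      amplitude_solver(pairs_for(tenc, grp5), dims, cal$max_amplitude_mm,
                       cal$tol)$amplitude_for(min(t5, 1)) else NA_real_
    ao <- if (nother > 0)
      amplitude_solver(pairs_for(tenc, !grp5), dims, cal$max_amplitude_mm,
                       cal$tol)$amplitude_for(max(to, 0.02)) else NA_real_
    seq_amp[[lab]] <- c(pirads5 = a5, other = ao)
    if (progress)
      message(sprintf("calibrated %s: amplitudes %.2f / %.2f mm", lab,
                      a5, ao))
    rm(tenc)
  }
  rm(phi_les)

  gland_amp_for <- function(lab, sdf_name, target) {
    phi <- vector("list", n)
    for (i in seq_len(n)) {
      phi[[i]] <- lapply(seq_len(R), function(r)
        .sdf_similarity_sample(truths[[i]][[sdf_name]], dims, sp,
                               truths[[i]]$gland_center,
                               ctx[[i]][[r]]$affine$trans,
                               ctx[[i]][[r]]$affine$scale))
    }
    tenc <- encode_label(lab, phi)
    amplitude_solver(pairs_for(tenc, rep(TRUE, n), use_mult = FALSE), dims,
                     cal$max_amplitude_mm, cal$tol)$amplitude_for(target)
  }
  amp_gland <- gland_amp_for("gland", "sdf_gland", config$gland_target_dsc)
  amp_tz <- gland_amp_for("tz", "sdf_tz", config$tz_target_dsc)
  list(sequences = seq_amp, gland = amp_gland, tz = amp_tz)
}

sample_case_meta <- function(config) {
  n <- config$n_cases
  set.seed(derive_seed(config$seed, 201))
  lesion_vol <- rlnorm(n, config$lesion_volume_ml["meanlog"],
                       config$lesion_volume_ml["sdlog"])
  # PI-RADS by (jittered) volume rank with the exact configured counts
  jit <- exp(rnorm(n, 0, config$pirads_rank_jitter))
  rk <- rank(lesion_vol * jit, ties.method = "first")
  counts <- config$pirads_counts
  pirads <- integer(n)
  pirads[rk <= counts[["3"]]] <- 3L
  pirads[rk > counts[["3"]] & rk <= counts[["3"]] + counts[["4"]]] <- 4L
  pirads[rk > counts[["3"]] + counts[["4"]]] <- 5L
  age <- pmin(pmax(round(rnorm(n, 69, 9)), 46), 90)
  psa <- round(rlnorm(n, log(8), 0.5), 1)
  isup <- sample(1:5, n, replace = TRUE, prob = c(18, 19, 9, 9, 9) / 64)
  data.frame(case_id = sprintf("case%03d", seq_len(n)), age = age,
             pirads = pirads, psa = psa, isup = isup,
             lesion_volume_ml = lesion_vol, stringsAsFactors = FALSE)
}

reader_ids <- function(n_readers) sprintf("R%d", seq_len(n_readers))

# Simulate all readers' structure sets for one case from its truth shapes.
simulate_case <- function(config, amplitudes, case_row, case_seed,
                          truth = NULL) {
  g <- config$geometry
  noise <- config$noise
  if (is.null(truth))
    truth <- generate_truth(config, case_seed, case_row$lesion_volume_ml)
  grp <- if (case_row$pirads == 5L) "pirads5" else "other"
  sets <- vector("list", config$n_readers)
  for (r in seq_len(config$n_readers)) {
    cx <- reader_affine_and_shared(case_seed, r, g, noise)
    del <- function(sdf, center, lab, amplitude) {
      f <- reader_structure_field(case_seed, r, lab, g, noise, cx$shared)
      v <- delineate(sdf, g, center, cx$affine, f, amplitude)
      if (!any(v)) {
        f <- reader_structure_field(case_seed, r, lab, g, noise, cx$shared,
                                    attempt = 2)
        v <- delineate(sdf, g, center, cx$affine, f, amplitude)
        if (!any(v))
          warn_segvar(sprintf("case %s reader %d %s: empty delineation",
                              case_row$case_id, r, lab),
                      "segvar_warning_empty_delineation")
      }
      v
    }
    gland_v <- del(truth$sdf_gland, truth$gland_center, "gland",
                   amplitudes$gland)
    tz_v <- del(truth$sdf_tz, truth$gland_center, "tz", amplitudes$tz) &
      gland_v
    pz_v <- gland_v & !tz_v
    mult <- case_amplitude_multiplier(config, truth$lesion_volume_ml)
    dil <- list()
    for (lab in delineated_sequence_labels())
      dil[[lab]] <- binary_mask(
        del(truth$sdf_lesion, truth$lesion_center, lab,
            amplitudes$sequences[[lab]][[grp]] * mult), g)
    sets[[r]] <- build_union_sets(structure_set(
      case_row$case_id, reader_ids(config$n_readers)[r],
      prostate = binary_mask(gland_v, g), tz = binary_mask(tz_v, g),
      pz = binary_mask(pz_v, g), dil = dil))
  }
  list(meta = case_row, readers = sets,
       truth = truth[c("gland_volume_ml", "tz_volume_ml",
                       "lesion_volume_ml", "lesion_center")])
}

#' Generate a synthetic multi-reader cohort
#'
#' Draws case metadata (PI-RADS assigned by jittered lesion-volume rank with
#' the exact configured counts), calibrates per-sequence field amplitudes to
#' the configured DSC targets, then simulates every case: ground-truth
#' gland/TZ/PZ/lesion shapes, per-reader delineations of all eight sequence
#' labels plus the gland structures, and the four derived union sets. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param output_dir if non-NULL, masks and `meta.csv` are written in the
#'   standard cohort layout and per-case masks are not kept in memory.
#' @param case_callback optional `function(case)` invoked per simulated case
#'   (for streaming analysis); when given, masks are not kept either.
#' @param progress print progress messages.
#' @return list with `meta` (data.frame), `amplitudes`, `config`, and
#'   `cases` (list of per-case results, `NULL` entries when streaming).
#' @export
generate_cohort <- function(config, output_dir = NULL, case_callback = NULL,
                            progress = FALSE) {
  meta <- sample_case_meta(config)
  truths <- lapply(seq_len(config$n_cases), function(i)
    generate_truth(config, derive_seed(config$seed, 500, i),
                   meta$lesion_volume_ml[i]))
  meta$gland_volume_ml <- vapply(truths, `[[`, 0, "gland_volume_ml")
  meta$lesion_truth_ml <- vapply(truths, `[[`, 0, "lesion_volume_ml")
  if (progress) message("truth shapes generated; calibrating amplitudes")
  amplitudes <- calibrate_cohort_amplitudes(config, meta, truths,
                                            progress = progress)
  keep <- is.null(output_dir) && is.null(case_callback)
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    cs <- simulate_case(config, amplitudes, meta[i, ],
                        derive_seed(config$seed, 500, i), truths[[i]])
    if (!is.null(output_dir))
      for (s in cs$readers) save_structure_set(s, output_dir)
    if (!is.null(case_callback)) case_callback(cs)
    if (keep) cases[[i]] <- cs
    if (progress && i %% 8 == 0)
      message(sprintf("simulated %d/%d cases", i, config$n_cases))
  }
  if (!is.null(output_dir)) {
    write.csv(meta[, c("case_id", "age", "pirads", "psa", "isup")],
              file.path(output_dir, "meta.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_cases = config$n_cases,
           amplitudes = amplitudes),
      file.path(output_dir, "config_used.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(meta = meta, amplitudes = amplitudes, config = config,
       cases = if (keep) cases else NULL)
}

#' Simulate a DCE series for one case
#'
#' Baseline frames followed by gamma-variate enhancement, strongest inside
#' the lesion, moderate in the gland, weak in the background, sampled at a
#' 5 s frame interval with additive Gaussian noise.
#'
#' @param lesion,gland `binary_mask` objects on a shared geometry.
#' @param seed RNG seed.
#' @param n_frames number of frames (default 40).
#' @param dt_s frame spacing in seconds (default 5).
#' @param n_baseline pre-contrast frames (default 4).
#' @param amplitudes named vector `c(lesion=, gland=, background=)` of peak
#'   relative enhancement per compartment.
#' @param noise_sd additive signal noise (baseline signal is 100).
#' @return a [dce_series()].
#' @export
generate_dce_series <- function(lesion, gland, seed = 1, n_frames = 40,
                                dt_s = 5, n_baseline = 4,
                                amplitudes = c(lesion = 1.2, gland = 0.6,
                                               background = 0.1),
                                noise_sd = 2) {
  check_compatible(lesion$geometry, gland$geometry)
  g <- lesion$geometry
  set.seed(seed)
  ts <- (seq_len(n_frames) - 1) * dt_s
  t0 <- n_baseline * dt_s
  tp <- 30; alpha <- 2
  gamma_var <- function(t) {
    u <- pmax(t - t0, 0) / tp
    (u * exp(1 - u))^alpha
  }
  amp <- array(amplitudes["background"], dim = g$shape)
  amp[gland$voxels] <- amplitudes["gland"]
  amp[lesion$voxels] <- amplitudes["lesion"]
  s0 <- 100
  frames <- array(0, c(g$shape, n_frames))
  gv <- gamma_var(ts)
  nvox <- prod(g$shape)
  for (k in seq_len(n_frames))
    frames[, , , k] <- s0 * (1 + amp * gv[k]) +
      if (noise_sd > 0) rnorm(nvox, 0, noise_sd) else 0
  dce_series(frames, ts, g)
}
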