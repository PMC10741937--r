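#' Dynamic contrast-enhanced (DCE) series
#'
#' A 4D signal array (space x time) on an [image_geometry()], with one
#' acquisition timestamp (seconds) per frame.
#'
#' @param frames 4D numeric array, dimensions `c(geometry$shape, n_frames)`.
#' @param timestamps numeric vector, seconds, strictly increasing, length
#'   equal to the number of frames (>= 3).
#' @param geometry an `image_geometry`.
#' @return an object of class `dce_series`.
#' @export
dce_series <- function(frames, timestamps, geometry) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 4L)
    abort_segvar("frames must be a 4D array", "segvar_error_not_4d")
  if (!identical(as.integer(d[1:3]), geometry$shape))
    abort_segvar("frame spatial shape does not match geometry",
                 "segvar_error_geometry")
  if (length(timestamps) != d[4] || length(timestamps) < 3)
    abort_segvar("need >= 3 frames with one timestamp each",
                 "segvar_error_dce_series")
  if (any(diff(timestamps) <= 0))
    abort_segvar("timestamps must be strictly increasing",
                 "segvar_error_dce_series")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 geometry = geometry), class = "dce_series")
}

#' Voxelwise pre-contrast baseline of a DCE series
#'
#' Mean of the first `n_baseline` frames at every voxel.
#'
#' @param series a `dce_series`.
#' @param n_baseline number of pre-contrast frames, `1 <= n_baseline <
#'   n_frames`.
#' @return 3D numeric array.
#' @export
baseline_estimate <- function(series, n_baseline) {
  nt <- length(series$timestamps)
  if (n_baseline < 1 || n_baseline >= nt)
    abort_segvar(sprintf("n_baseline must be in [1, %d)", nt),
                 "segvar_error_baseline_range")
  sh <- series$geometry$shape
  m <- matrix(series$frames, ncol = nt)
  array(rowMeans(m[, seq_len(n_baseline), drop = FALSE]), dim = sh)
}

#' Detect the bolus arrival frame
#'
#' Earliest frame whose mean signal over `roi` exceeds the pre-contrast
#' baseline mean by a factor `1 + threshold_frac`; if no frame exceeds it,
#' falls back to the first post-baseline frame (`n_baseline + 1`).
#'
#' @param series a `dce_series`.
#' @param threshold_frac fractional rise over baseline that defines arrival.
#' @param n_baseline pre-contrast frame count.
#' @param roi optional `binary_mask` (e.g. the gland) over which frame means
#'   are taken; defaults to the whole volume.
#' @return frame index (1-based).
#' @export
detect_bolus_arrival <- function(series, threshold_frac = 0.1, n_baseline = 3,
                                 roi = NULL) {
  nt <- length(series$timestamps)
  if (n_baseline < 1 || n_baseline >= nt)
    abort_segvar(sprintf("n_baseline must be in [1, %d)", nt),
                 "segvar_error_baseline_range")
  m <- matrix(series$frames, ncol = nt)
  if (!is.null(roi)) {
    check_compatible(series$geometry, roi$geometry)
    m <- m[as.vector(roi$voxels), , drop = FALSE]
  }
  frame_means <- colMeans(m)
  base <- mean(frame_means[seq_len(n_baseline)])
  hit <- which(frame_means > base * (1 + threshold_frac))
  if (length(hit) == 0) return(n_baseline + 1L)
  as.integer(hit[1])
}

# Trapezoid weights for integrating a piecewise-linear signal sampled at
# `knots` over the window [t0, t1]; window endpoints falling between knots
# contribute via linear interpolation, so integrals are additive over
# adjacent windows.
trapezoid_weights <- function(knots, t0, t1) {
  w <- numeric(length(knots))
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    lo <- max(a, t0); hi <- min(b, t1)
    if (hi <= lo) next
    h <- b - a
    # value at point t within [a,b]: ((b-t)*y_i + (t-a)*y_{i+1})/h
    # integral over [lo,hi] of the linear interpolant:
    mid <- (lo + hi) / 2
    len <- hi - lo
    w[i] <- w[i] + len * (b - mid) / h
    w[i + 1] <- w[i + 1] + len * (mid - a) / h
  }
  w
}

#' Initial area under the gadolinium curve (IAUCG) map
#'
#' Voxelwise trapezoidal integral of the relative enhancement
#' `(S(t) - S0)/S0` from the bolus-arrival time over an integration window,
#' on the actual acquisition timestamps. Negative enhancement contributes as
#' computed (no clipping). Voxels with zero baseline are flagged missing
#' (`NA`).
#'
#' @param series a `dce_series`.
#' @param arrival arrival frame index (1-based), e.g. from
#'   [detect_bolus_arrival()].
#' @param window_s integration window length in seconds (default 60);
#'   truncated with a warning if it extends past the last frame.
#' @param n_baseline pre-contrast frame count used for the baseline map.
#' @return an object of class `iaucg_map`: list with `values` (3D array,
#'   signal x seconds in relative-enhancement units), `geometry`,
#'   `window_s`.
#' @export
compute_iaucg <- function(series, arrival, window_s = 60, n_baseline = 3) {
  nt <- length(series$timestamps)
  if (arrival < 1 || arrival > nt)
    abort_segvar("arrival frame out of range", "segvar_error_arrival_range")
  t0 <- series$timestamps[arrival]
  t1 <- t0 + window_s
  tmax <- series$timestamps[nt]
  if (t1 > tmax + 1e-9) {
    warn_segvar(sprintf(
      "integration window truncated at the last frame (%.1f of %.1f s)",
      tmax - t0, window_s), "segvar_warning_window_truncated")
    t1 <- tmax
  }
  s0 <- as.vector(baseline_estimate(series, n_baseline))
  m <- matrix(series$frames, ncol = nt)
  enh <- (m - s0) / s0
  enh[s0 == 0, ] <- NA_real_
  w <- trapezoid_weights(series$timestamps, t0, t1)
  vals <- as.vector(enh %*% w)
  structure(list(values = array(vals, dim = series$geometry$shape),
                 geometry = series$geometry, window_s = t1 - t0),
            class = "iaucg_map")
}

#' @export
print.iaucg_map <- function(x, ...) {
  cat(sprintf("<iaucg_map> %s grid, %.0f s window, mean %.2f\n",
              paste(x$geometry$shape, collapse = "x"), x$window_s,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}
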