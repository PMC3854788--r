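#' Preprocessing configuration
#'
#' Bundles the parameters of the stack preprocessing chain:
#' isotropic resampling, Gaussian denoising, percentile contrast stretch and
#' Laplacian boundary enhancement.
#'
#' @param target_spacing_um isotropic voxel edge after resampling, um.
#' @param gaussian_sigma_um SD of the denoising Gaussian, um.
#' @param histogram_stretch_percentiles length-2 numeric `(low, high)` in
#'   percent, `0 <= low < high <= 100`. The default `(0.5, 100)` subtracts
#'   the background pedestal without clipping bright voxels: an upper
#'   percentile below 100 saturates spot cores into plateaus whose
#'   subsequent Laplacian overshoot rings outshine them, fragmenting seed
#'   detection, and it also destroys the intensity linearity that per-spot
#'   brightness comparisons rely on.
#' @param laplacian_weight non-negative weight of the subtracted 6-neighbour
#'   Laplacian.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing_um = 0.2,
                              gaussian_sigma_um = 0.2,
                              histogram_stretch_percentiles = c(0.5, 100),
                              laplacian_weight = 1.0) {
  p <- histogram_stretch_percentiles
  if (length(p) != 2L || p[1] < 0 || p[2] > 100 || p[1] >= p[2])
    stop("percentiles must satisfy 0 <= low < high <= 100")
  if (target_spacing_um <= 0 || gaussian_sigma_um <= 0 || laplacian_weight < 0)
    stop("invalid preprocess parameter")
  structure(list(target_spacing_um = target_spacing_um,
                 gaussian_sigma_um = gaussian_sigma_um,
                 histogram_stretch_percentiles = p,
                 laplacian_weight = laplacian_weight),
            class = "preprocess_config")
}

# linear interpolation of a 3D array along its first axis at fractional
# (0-based) positions `fi`; positions are snapped to the lattice when within
# 1e-9 of an integer so that identity resampling is exact.
interp_axis1 <- function(arr, fi) {
  n <- dim(arr)[1]
  fi <- pmin(pmax(fi, 0), n - 1)
  snap <- abs(fi - round(fi)) < 1e-9
  fi[snap] <- round(fi[snap])
  i0 <- pmin(floor(fi), n - 1)
  w <- fi - i0
  i1 <- pmin(i0 + 1, n - 1)
  a0 <- arr[i0 + 1, , , drop = FALSE]
  a1 <- arr[i1 + 1, , , drop = FALSE]
  # recycling along the fastest-varying (first) dimension; the a0 + w*(a1-a0)
  # form is exact for constant fields and at lattice points
  a0 + (a1 - a0) * w
}

#' Resample a stack to isotropic voxels
#'
#' Confocal stacks are typically acquired with coarser axial (z) than lateral
#' spacing. This resamples the grid by trilinear interpolation onto an
#' isotropic lattice of edge `target_spacing_um`, evaluated at the new voxel
#' centres expressed in the input's physical frame. The physical extent is
#' preserved to within one voxel.
#'
#' @param grid a [voxel_grid()].
#' @param target_spacing_um positive scalar, um.
#' @return a [voxel_grid()] with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(grid, target_spacing_um = 0.2) {
  stopifnot_grid(grid)
  t <- target_spacing_um
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("`target_spacing_um` must be a positive scalar")
  d <- dim(grid$data)
  extent <- (d - 1) * grid$spacing_um
  if (any(t > extent + 1e-9 & d > 1) || all(d == 1))
    stop("target spacing ", t, " um exceeds the physical image extent (",
         paste(format(extent), collapse = " x "), " um)")
  n_new <- floor(extent / t + 1e-9) + 1
  out <- grid$data
  for (ax in 1:3) {
    fi <- (seq_len(n_new[ax]) - 1) * t / grid$spacing_um[ax]
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    out <- aperm(interp_axis1(aperm(out, perm), fi), order(perm))
  }
  voxel_grid(out, spacing_um = rep(t, 3), origin_um = grid$origin_um)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Separable convolution with an isotropic Gaussian of standard deviation
#' `sigma_um` (converted to voxels), truncated at 3 SD, with symmetric
#' (reflect) boundary handling so the local mean is preserved near edges.
#'
#' @param grid an isotropic [voxel_grid()] (resample first).
#' @param sigma_um positive scalar, um.
#' @return a smoothed [voxel_grid()].
#' @export
smooth_gaussian <- function(grid, sigma_um = 0.2) {
  stopifnot_grid(grid)
  sp <- grid$spacing_um
  if (diff(range(sp)) > 1e-9)
    stop("grid is anisotropic; apply resample_isotropic() first")
  if (sigma_um <= 0) stop("`sigma_um` must be positive")
  k <- gaussian_kernel_1d(sigma_um / sp[1])
  d <- dim(grid$data)
  x <- as.numeric(grid$data)
  for (ax in 0:2) x <- convolve_axis_cpp(x, d, k, ax)
  voxel_grid(array(x, d), spacing_um = sp, origin_um = grid$origin_um)
}

#' Percentile contrast stretch
#'
#' Affine enhancement of the intensity histogram: the `low` percentile maps
#' to 0 and the `high` percentile to the previous maximum; values outside
#' are clipped. The transform is monotone non-decreasing, so intensity ranks
#' are preserved within the clip range. With `percentiles = c(p, 100)` the
#' upper clip is inactive and the operation reduces to background
#' subtraction plus rescaling, which leaves intensity ratios between spots
#' intact — the form used on the quantification path (see
#' [run_image_pipeline()]).
#'
#' @param grid a [voxel_grid()].
#' @param percentiles length-2 numeric `(low, high)` in percent.
#' @return an enhanced [voxel_grid()]. A constant grid is returned unchanged
#'   with a warning.
#' @export
enhance_histogram <- function(grid, percentiles = c(0.5, 99.5)) {
  stopifnot_grid(grid)
  if (length(percentiles) != 2L || percentiles[1] < 0 ||
      percentiles[2] > 100 || percentiles[1] >= percentiles[2])
    stop("percentiles must satisfy 0 <= low < high <= 100")
  x <- grid$data
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant grid: histogram enhancement skipped")
    return(grid)
  }
  q <- stats::quantile(x, percentiles / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate percentile range: histogram enhancement skipped")
    return(grid)
  }
  m <- rng[2]
  y <- (x - q[1]) * (m / (q[2] - q[1]))
  y[y < 0] <- 0
  y[y > m] <- m
  voxel_grid(y, spacing_um = grid$spacing_um, origin_um = grid$origin_um)
}

# 6-neighbour discrete Laplacian with replicated-edge (Neumann) boundaries,
# so a constant field has Laplacian exactly 0 everywhere.
laplacian6 <- function(arr) {
  d <- dim(arr)
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    idx[[ax]] <- i
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  acc <- -6 * arr
  for (ax in 1:3) acc <- acc + shift(arr, ax, 1L) + shift(arr, ax, -1L)
  acc
}

#' Laplacian boundary enhancement
#'
#' Unsharp-style sharpening: subtracts `weight` times the 6-neighbour
#' discrete Laplacian, which steepens intensity boundaries between adjacent
#' spots. Output is clipped at 0.
#'
#' @param grid an isotropic [voxel_grid()].
#' @param weight non-negative scalar; 0 is the identity.
#' @return an enhanced [voxel_grid()].
#' @export
enhance_laplacian <- function(grid, weight = 1.0) {
  stopifnot_grid(grid)
  if (weight < 0) stop("`weight` must be non-negative")
  if (weight == 0) return(grid)
  y <- grid$data - weight * laplacian6(grid$data)
  y[y < 0] <- 0
  voxel_grid(y, spacing_um = grid$spacing_um, origin_um = grid$origin_um)
}

#' Normalize intensities to a unit maximum
#'
#' Divides the whole grid by its global maximum so that `max(I) == 1`, and
#' flags the grid as normalized. Idempotent. For multi-stack group
#' comparisons use a common (cohort) maximum instead — see
#' [run_image_pipeline()] — because per-stack normalization erases
#' between-group intensity differences.
#'
#' @param grid a [voxel_grid()] with positive maximum.
#' @param max_value the normalization constant; defaults to the grid's own
#'   maximum. Supply a cohort-wide maximum for comparable stacks.
#' @return a normalized [voxel_grid()].
#' @export
normalize_intensity <- function(grid, max_value = NULL) {
  stopifnot_grid(grid)
  mx <- if (is.null(max_value)) max(grid$data) else max_value
  if (!is.finite(mx) || mx <= 0) stop("empty image")
  voxel_grid(grid$data / mx, spacing_um = grid$spacing_um,
             origin_um = grid$origin_um, normalized = TRUE)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: resample to isotropic voxels, Gaussian smoothing,
#' percentile contrast stretch, Laplacian boundary enhancement, max
#' normalization. Deterministic: rerunning with the same configuration
#' reproduces the output bit for bit.
#'
#' @param grid a [voxel_grid()].
#' @param config a [preprocess_config()].
#' @param normalize logical; apply the final max normalization (skip it when
#'   a cohort-wide constant will be applied later).
#' @return a preprocessed [voxel_grid()].
#' @export
preprocess_stack <- function(grid, config = preprocess_config(),
                             normalize = TRUE) {
  g <- resample_isotropic(grid, config$target_spacing_um)
  g <- smooth_gaussian(g, config$gaussian_sigma_um)
  g <- enhance_histogram(g, config$histogram_stretch_percentiles)
  g <- enhance_laplacian(g, config$laplacian_weight)
  if (normalize) g <- normalize_intensity(g)
  g
}
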