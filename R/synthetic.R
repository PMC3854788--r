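#' Specification of a synthetic confocal scene
#'
#' Describes a ground-truthed 3D test scene emulating immunofluorescence
#' stacks of cytoplasmic puncta: a diffuse background plus `n_spots`
#' isotropic 3D Gaussian spots at random, mutually separated positions,
#' sampled on an (optionally anisotropic) voxel lattice and corrupted by a
#' chosen noise model.
#'
#' The default spacing `(1.0, 0.2, 0.2)` um `(z, y, x)` mimics a confocal
#' z-step coarser than the lateral pixel size, so the isotropic resampling
#' stage is exercised nontrivially.
#'
#' @param shape_voxels integer length-3 `(z, y, x)`.
#' @param voxel_spacing_um positive numeric length-3 `(z, y, x)`, um.
#' @param n_spots non-negative integer.
#' @param amplitude_range positive length-2 interval of spot amplitudes
#'   (arbitrary fluorescence units); lower bound must exceed
#'   `background_level`.
#' @param sigma_um_range positive length-2 interval of isotropic Gaussian SDs
#'   in um.
#' @param min_separation_um minimal pairwise centre separation; must be at
#'   least twice the largest sigma so ground-truth spots stay resolvable.
#' @param background_level non-negative diffuse background.
#' @param noise_model `"gaussian"` (additive, `sd`) or `"poisson-gaussian"`
#'   (photon shot noise with `gain` plus read noise `read_sd`). Gaussian
#'   noise with `sd = 0` gives a noiseless scene.
#' @param noise_params named list of the noise model's parameters.
#' @param rng_seed integer seed; scenes are bit-reproducible for a fixed
#'   seed (Mersenne-Twister).
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(shape_voxels = c(10, 64, 64),
                       voxel_spacing_um = c(1.0, 0.2, 0.2),
                       n_spots = 8,
                       amplitude_range = c(80, 120),
                       sigma_um_range = c(0.25, 0.4),
                       min_separation_um = 2.0,
                       background_level = 10,
                       noise_model = c("gaussian", "poisson-gaussian"),
                       noise_params = NULL,
                       rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(noise_params))
    noise_params <- switch(noise_model,
                           "gaussian" = list(sd = 10),
                           "poisson-gaussian" = list(gain = 2, read_sd = 5))
  if (length(shape_voxels) != 3L || any(shape_voxels < 1))
    stop("`shape_voxels` must be three positive integers")
  if (n_spots < 0) stop("`n_spots` must be non-negative")
  if (n_spots > 0) {
    if (min_separation_um < 2 * max(sigma_um_range))
      stop("`min_separation_um` must be >= 2 * max(sigma_um_range) ",
           "so that ground-truth spots are resolvable")
    if (min(amplitude_range) <= background_level)
      stop("`amplitude_range` lower bound must exceed `background_level`")
  }
  structure(list(shape_voxels = as.integer(shape_voxels),
                 voxel_spacing_um = as.numeric(voxel_spacing_um),
                 n_spots = as.integer(n_spots),
                 amplitude_range = as.numeric(amplitude_range),
                 sigma_um_range = as.numeric(sigma_um_range),
                 min_separation_um = min_separation_um,
                 background_level = background_level,
                 noise_model = noise_model,
                 noise_params = noise_params,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# rejection-sample spot centres honouring the pairwise separation; a margin
# of 2*sigma_max keeps spot cores inside the field of view
draw_scene_params <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$n_spots
    extent <- (spec$shape_voxels - 1) * spec$voxel_spacing_um
    margin <- 2 * max(spec$sigma_um_range)
    lo <- pmin(margin, extent / 2)
    hi <- pmax(extent - margin, extent / 2)
    centers <- matrix(0, n, 3, dimnames = list(NULL, c("z", "y", "x")))
    budget <- 1000L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(budget)) {
        cand <- stats::runif(3, lo, hi)
        if (i == 1L || all(sqrt(colSums((t(centers[seq_len(i - 1), ,
                 drop = FALSE]) - cand)^2)) >= spec$min_separation_um)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place spot ", i, " after ", budget,
             " attempts: min_separation_um = ", spec$min_separation_um,
             " um is too large for the field of view")
    }
    list(centers_um = centers,
         amplitudes = stats::runif(n, spec$amplitude_range[1],
                                   spec$amplitude_range[2]),
         sigmas_um = stats::runif(n, spec$sigma_um_range[1],
                                  spec$sigma_um_range[2]))
  })
}

# render background + sum of Gaussian spots at voxel centres (no noise)
render_scene <- function(spec, scene) {
  d <- spec$shape_voxels
  sp <- spec$voxel_spacing_um
  arr <- array(spec$background_level, dim = d)
  zc <- (seq_len(d[1]) - 1) * sp[1]
  yc <- (seq_len(d[2]) - 1) * sp[2]
  xc <- (seq_len(d[3]) - 1) * sp[3]
  for (i in seq_len(spec$n_spots)) {
    s <- scene$sigmas_um[i]
    c_ <- scene$centers_um[i, ]
    gz <- exp(-(zc - c_[1])^2 / (2 * s^2))
    gy <- exp(-(yc - c_[2])^2 / (2 * s^2))
    gx <- exp(-(xc - c_[3])^2 / (2 * s^2))
    arr <- arr + scene$amplitudes[i] *
      (gz %o% gy %o% gx)
  }
  arr
}

apply_noise <- function(arr, spec, seed) {
  with_seed(seed, {
    n <- length(arr)
    if (spec$noise_model == "gaussian") {
      sd <- spec$noise_params$sd
      if (sd > 0) arr <- arr + stats::rnorm(n, 0, sd)
    } else {
      g <- spec$noise_params$gain
      rs <- spec$noise_params$read_sd
      arr <- array(g * stats::rpois(n, pmax(arr, 0) / g), dim = dim(arr))
      if (rs > 0) arr <- arr + stats::rnorm(n, 0, rs)
    }
    arr
  })
}

#' Render a ground-truth label map
#'
#' Assigns each voxel to its nearest spot centre if the voxel centre lies
#' within two standard deviations of that spot; all other voxels are 0.
#'
#' @param ground_truth a `ground_truth` list (see [generate_stack()]).
#' @param shape_voxels integer length-3 grid shape `(z, y, x)`.
#' @param spacing_um numeric length-3 voxel spacing, um.
#' @return a `spot_label_map` on the requested grid.
#' @export
render_truth_labels <- function(ground_truth, shape_voxels, spacing_um) {
  d <- as.integer(shape_voxels)
  n <- nrow(ground_truth$centers_um)
  lab <- array(0L, dim = d)
  if (n > 0) {
    zc <- (seq_len(d[1]) - 1) * spacing_um[1]
    yc <- (seq_len(d[2]) - 1) * spacing_um[2]
    xc <- (seq_len(d[3]) - 1) * spacing_um[3]
    best <- array(Inf, dim = d)
    arg <- array(0L, dim = d)
    one <- function(v) array(1, dim = length(v))
    for (i in seq_len(n)) {
      c_ <- ground_truth$centers_um[i, ]
      d2 <- (zc - c_[1])^2 %o% one(yc) %o% one(xc) +
        one(zc) %o% (yc - c_[2])^2 %o% one(xc) +
        one(zc) %o% one(yc) %o% (xc - c_[3])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      arg[upd] <- i
    }
    sel <- arg > 0 & best <= (2 * ground_truth$sigmas_um[pmax(arg, 1L)])^2
    lab[sel] <- arg[sel]
  }
  new_spot_label_map(lab, n_spots = n, foreground_threshold = NA_real_)
}

#' Generate a synthetic confocal stack with ground truth
#'
#' Renders `background + sum of Gaussian spots` at voxel centres, corrupted
#' by the configured noise model. Deterministic for a fixed `rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `grid` (a [voxel_grid()]) and `ground_truth`
#'   (class `ground_truth`: `centers_um` (n x 3 matrix, z/y/x), `amplitudes`,
#'   `sigmas_um`, and `true_label_map` rendered at the scene's native grid).
#' @examples
#' st <- generate_stack(scene_spec(n_spots = 3, rng_seed = 7))
#' st$grid
#' st$ground_truth$centers_um
#' @export
generate_stack <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("expected a `scene_spec`")
  scene <- draw_scene_params(spec, spec$rng_seed)
  arr <- render_scene(spec, scene)
  arr <- apply_noise(arr, spec, spec$rng_seed + 1L)
  gt <- structure(list(centers_um = scene$centers_um,
                       amplitudes = scene$amplitudes,
                       sigmas_um = scene$sigmas_um,
                       true_label_map = render_truth_labels(
                         scene, spec$shape_voxels, spec$voxel_spacing_um)),
                  class = "ground_truth")
  list(grid = voxel_grid(arr, spacing_um = spec$voxel_spacing_um),
       ground_truth = gt)
}

#' Generate a two-condition synthetic experiment
#'
#' Emulates a genotype comparison: group B stacks share the scene geometry
#' (centres, widths) of their group A counterparts but every spot amplitude
#' is multiplied by `amplitude_scale`, as when a mutation reduces the
#' abundance of the imaged protein. Noise is drawn independently per stack;
#' all per-stack seeds derive deterministically from `spec$rng_seed`.
#'
#' @param spec a [scene_spec()] describing the group A stacks.
#' @param amplitude_scale positive scalar multiplying group B amplitudes.
#' @param n_stacks_per_group positive integer.
#' @return a list with elements `A` and `B`, each a list of
#'   `list(grid, ground_truth)` as returned by [generate_stack()].
#' @export
generate_two_condition_experiment <- function(spec, amplitude_scale,
                                              n_stacks_per_group) {
  if (!inherits(spec, "scene_spec")) stop("expected a `scene_spec`")
  if (!is.numeric(amplitude_scale) || amplitude_scale <= 0)
    stop("`amplitude_scale` must be positive")
  if (n_stacks_per_group < 1) stop("`n_stacks_per_group` must be >= 1")
  out <- list(A = vector("list", n_stacks_per_group),
              B = vector("list", n_stacks_per_group))
  for (j in seq_len(n_stacks_per_group)) {
    scene_seed <- spec$rng_seed + 1009L * j
    scene <- draw_scene_params(spec, scene_seed)
    sceneB <- scene
    sceneB$amplitudes <- scene$amplitudes * amplitude_scale
    for (grp in c("A", "B")) {
      sc <- if (grp == "A") scene else sceneB
      arr <- render_scene(spec, sc)
      arr <- apply_noise(arr, spec, scene_seed + if (grp == "A") 1L else 2L)
      gt <- structure(list(centers_um = sc$centers_um,
                           amplitudes = sc$amplitudes,
                           sigmas_um = sc$sigmas_um,
                           true_label_map = render_truth_labels(
                             sc, spec$shape_voxels, spec$voxel_spacing_um)),
                      class = "ground_truth")
      out[[grp]][[j]] <- list(grid = voxel_grid(arr,
                                spacing_um = spec$voxel_spacing_um),
                              ground_truth = gt)
    }
  }
  out
}

#' Write a synthetic stack and its ground truth to disk
#'
#' The stack goes out as a multi-page TIFF with a `key=value` spacing
#' sidecar, the ground truth as a CSV (one row per spot) and the true label
#' map as a 16-bit TIFF.
#'
#' @param stack a `list(grid, ground_truth)` from [generate_stack()].
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return the paths written, invisibly.
#' @export
write_synthetic_stack <- function(stack, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".tif"))
  write_stack(stack$grid, p_img)
  gt <- stack$ground_truth
  p_csv <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(data.frame(id = seq_len(nrow(gt$centers_um)),
                              z_um = gt$centers_um[, 1],
                              y_um = gt$centers_um[, 2],
                              x_um = gt$centers_um[, 3],
                              amplitude = gt$amplitudes,
                              sigma_um = gt$sigmas_um),
                   p_csv, row.names = FALSE)
  p_lab <- file.path(dir, paste0(stem, "_truth_labels.tif"))
  write_label_map(gt$true_label_map, p_lab)
  invisible(c(image = p_img, truth = p_csv, labels = p_lab))
}
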