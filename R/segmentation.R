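new_spot_label_map <- function(labels, n_spots, foreground_threshold,
                               unreachable = 0L, n_foreground = NA_integer_) {
  structure(list(labels = labels, n_spots = as.integer(n_spots),
                 foreground_threshold = foreground_threshold,
                 unreachable = as.integer(unreachable),
                 n_foreground = as.integer(n_foreground)),
            class = "spot_label_map")
}

#' @export
print.spot_label_map <- function(x, ...) {
  cat(sprintf("<spot_label_map> %s voxels, %d segments, threshold %s\n",
              paste(dim(x$labels), collapse = " x "), x$n_spots,
              format(x$foreground_threshold)))
  invisible(x)
}

# maximum over the 26-neighbourhood, with -Inf beyond the image border
neighbor_max <- function(arr) {
  d <- dim(arr)
  shift_pad <- function(a, dz, dy, dx) {
    out <- array(-Inf, dim = d)
    src <- function(n, s) max(1, 1 - s):min(n, n - s)
    iz <- src(d[1], dz); iy <- src(d[2], dy); ix <- src(d[3], dx)
    out[iz + dz, iy + dy, ix + dx] <- a[iz, iy, ix]
    out
  }
  nb <- array(-Inf, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pmax(nb, shift_pad(arr, dz, dy, dx))
  }
  nb
}

#' Otsu threshold of a voxel grid
#'
#' Classic between-class-variance maximization over a binned intensity
#' histogram; used as the default foreground threshold for segmentation.
#'
#' @param grid a [voxel_grid()].
#' @param n_bins number of histogram bins.
#' @return a scalar threshold on the grid's intensity scale.
#' @export
otsu_threshold <- function(grid, n_bins = 256L) {
  stopifnot_grid(grid)
  x <- as.numeric(grid$data)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(pmax(
    findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                 rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

#' Robust foreground threshold
#'
#' [otsu_threshold()] maximizes between-class variance, which can collapse
#' into a split of the background noise distribution when spots occupy a
#' tiny volume fraction. This floors it at the upper edge of the background
#' noise band, `median + n_mad * 1.4826 * MAD`, so the foreground always
#' clears the noise. Used as the pipeline's default.
#'
#' @param grid a [voxel_grid()].
#' @param n_mad number of (normal-consistent) MADs above the median.
#' @return a scalar threshold.
#' @export
robust_fg_threshold <- function(grid, n_mad = 5) {
  stopifnot_grid(grid)
  x <- as.numeric(grid$data)
  max(otsu_threshold(grid),
      stats::median(x) + n_mad * stats::mad(x))
}

#' Detect spot seeds at local intensity maxima
#'
#' Seeds are the 26-neighbourhood local maxima of a normalized grid with
#' intensity at least `h_min`. Plateaus (connected constant-valued maxima)
#' contribute a single seed at the plateau centroid rounded to the nearest
#' voxel; a plateau counts as a maximum only if every voxel adjacent to it
#' is strictly darker, so a flat field yields no seeds. Maxima closer than
#' `min_separation_um` are merged, keeping the brighter seed (ties: the
#' smaller `(z, y, x)` lexicographic index).
#'
#' @param grid a normalized, isotropic [voxel_grid()].
#' @param h_min minimal seed intensity in `[0, 1]`.
#' @param min_separation_um merge radius in um; 0 disables merging.
#' @return a list of class `seed_set` with `seeds` (n x 3 integer matrix of
#'   1-based voxel indices, columns z/y/x) and `intensities`.
#' @export
detect_seeds <- function(grid, h_min = 0.1, min_separation_um = 0.4) {
  stopifnot_grid(grid)
  if (!grid$normalized) stop("grid must be normalized (see normalize_intensity)")
  arr <- grid$data
  d <- dim(arr)
  cand <- arr >= neighbor_max(arr)
  empty <- function() structure(
    list(seeds = matrix(integer(), 0, 3,
                        dimnames = list(NULL, c("z", "y", "x"))),
         intensities = numeric()), class = "seed_set")
  if (!any(cand)) return(empty())
  comp <- array(label_components_cpp(as.logical(cand), d), dim = d)
  idx_by_comp <- split(which(cand), comp[cand])
  seeds <- matrix(numeric(), 0, 3)
  vals <- numeric()
  for (k in as.integer(names(idx_by_comp))) {
    idx <- idx_by_comp[[as.character(k)]]
    v <- arr[idx[1]]
    if (v < h_min) next
    coords <- arrayInd(idx, d)
    # exterior check: every neighbour outside the plateau strictly darker
    ok <- TRUE
    has_exterior <- FALSE
    for (dz in -1:1) { for (dy in -1:1) { for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      nb <- coords + matrix(c(dz, dy, dx), nrow(coords), 3, byrow = TRUE)
      inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(inside)) next
      nbi <- nb[inside, , drop = FALSE]
      lin <- nbi[, 1] + d[1] * ((nbi[, 2] - 1) + d[2] * (nbi[, 3] - 1))
      ext <- comp[lin] != k
      if (any(ext)) {
        has_exterior <- TRUE
        if (any(arr[lin[ext]] >= v)) { ok <- FALSE; break }
      }
    }; if (!ok) break }; if (!ok) break }
    if (!ok || !has_exterior) next
    w <- arr[idx]
    ctr <- round(colSums(coords * w) / sum(w))
    ctr <- pmin(pmax(ctr, 1), d)
    seeds <- rbind(seeds, ctr)
    vals <- c(vals, v)
  }
  if (nrow(seeds) == 0L) return(empty())
  # merge within min_separation_um, brighter first, lexicographic tie-break
  ord <- order(-vals, seeds[, 1], seeds[, 2], seeds[, 3])
  sp <- grid$spacing_um
  keep <- integer()
  for (i in ord) {
    pos <- (seeds[i, ] - 1) * sp
    if (length(keep) == 0L ||
        all(sqrt(colSums((t((seeds[keep, , drop = FALSE] - 1) *
          rep(sp, each = length(keep))) - pos)^2)) >= min_separation_um))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  out <- seeds[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("z", "y", "x")
  rownames(out) <- NULL
  structure(list(seeds = out, intensities = vals[keep]), class = "seed_set")
}

#' Segment spots by competitive geodesic front propagation
#'
#' Realizes a seeded evolving-generalized-Voronoi-diagram partition of the
#' foreground: a front grows from every seed simultaneously, moving only
#' through foreground voxels (26-connectivity), and each voxel joins the
#' seed whose front arrives at minimal geodesic cost. The local cost of
#' traversing a voxel `x` for the front of seed `s` is
#' `1 + lambda * max(0, I(s) - I(x))`, so fronts advance fastest downhill
#' from their seed and segment boundaries settle on intensity ridges. Equal
#' arrival costs resolve to the smaller seed index, making the output
#' deterministic. Foreground voxels unreachable from every seed are left as
#' background and counted in the result.
#'
#' @param grid a normalized [voxel_grid()].
#' @param seeds a `seed_set` from [detect_seeds()].
#' @param foreground_threshold scalar in `[0, 1]`; defaults to
#'   [otsu_threshold()] of the grid.
#' @param lambda non-negative intensity weighting of the traversal cost.
#' @return a `spot_label_map`: integer array `labels` (0 = background,
#'   `1..L` = segments), `n_spots`, the threshold used, and the count of
#'   unreachable foreground voxels.
#' @export
segment_spots <- function(grid, seeds, foreground_threshold = NULL,
                          lambda = 5) {
  stopifnot_grid(grid)
  if (!grid$normalized) stop("grid must be normalized (see normalize_intensity)")
  if (!inherits(seeds, "seed_set")) stop("expected a `seed_set`")
  if (is.null(foreground_threshold)) foreground_threshold <- otsu_threshold(grid)
  d <- dim(grid$data)
  fg <- grid$data >= foreground_threshold
  L <- nrow(seeds$seeds)
  if (L == 0L) {
    if (any(fg)) stop("empty seed set with nonempty foreground")
    return(new_spot_label_map(array(0L, dim = d), 0L, foreground_threshold,
                              n_foreground = 0L))
  }
  si <- seeds$seeds
  lin0 <- (si[, 1] - 1L) + d[1] * ((si[, 2] - 1L) + d[2] * (si[, 3] - 1L))
  below <- which(!fg[lin0 + 1L])
  if (length(below))
    stop("seed ", below[1], " at voxel (",
         paste(si[below[1], ], collapse = ", "),
         ") lies below the foreground threshold ",
         format(foreground_threshold))
  seed_int <- grid$data[lin0 + 1L]
  lab <- propagate_labels_cpp(as.numeric(grid$data), as.logical(fg), d,
                              as.integer(lin0), as.numeric(seed_int),
                              as.numeric(lambda))
  lab <- array(lab, dim = d)
  unreach <- sum(fg & lab == 0L)
  if (unreach > 0)
    message(unreach, " foreground voxel(s) unreachable from any seed; ",
            "relabelled as background")
  new_spot_label_map(lab, L, foreground_threshold, unreach,
                     n_foreground = sum(fg))
}

#' Check that a segment is a connected region
#'
#' A segment is connected if any two of its voxels are joined by a path of
#' 26-adjacent voxels lying entirely inside the segment; equivalently, flood
#' fill from one voxel reaches all of them.
#'
#' @param labels a `spot_label_map`.
#' @param l a positive label present in the map.
#' @return `TRUE` if segment `l` is 26-connected.
#' @export
check_connected <- function(labels, l) {
  if (!inherits(labels, "spot_label_map")) stop("expected a `spot_label_map`")
  mask <- labels$labels == l
  if (!any(mask)) stop("label ", l, " absent from the label map")
  cc <- label_components_cpp(as.logical(mask), dim(labels$labels))
  max(cc) == 1L
}
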