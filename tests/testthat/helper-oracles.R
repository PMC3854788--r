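# Independent oracles and small builders used across the test files.

# Brute-force per-seed Dijkstra over all voxels of a 3D grid (pure R,
# O(V^2) selection), followed by argmin labelling with smaller-seed
# tie-break. Mirrors the definition of the competitive geodesic partition,
# not its implementation.
oracle_labels <- function(intensity, foreground, seeds, lambda) {
  d <- dim(intensity)
  n <- length(intensity)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  steps <- sqrt(rowSums(offs^2))
  coord <- arrayInd(seq_len(n), d)
  best <- rep(Inf, n)
  label <- integer(n)
  for (s in seq_len(nrow(seeds))) {
    s_lin <- seeds[s, 1] + d[1] * ((seeds[s, 2] - 1) + d[2] * (seeds[s, 3] - 1))
    Is <- intensity[s_lin]
    dist <- rep(Inf, n)
    dist[s_lin] <- 0
    done <- !as.vector(foreground)
    done[s_lin] <- FALSE
    repeat {
      dd <- dist
      dd[done] <- Inf
      u <- which.min(dd)
      if (!is.finite(dd[u])) break
      done[u] <- TRUE
      for (k in seq_len(nrow(offs))) {
        v <- coord[u, ] + offs[k, ]
        if (any(v < 1) || any(v > d)) next
        vl <- v[1] + d[1] * ((v[2] - 1) + d[2] * (v[3] - 1))
        if (!foreground[vl]) next
        w <- 1 + lambda * max(0, Is - intensity[vl])
        nd <- dist[u] + steps[k] * w
        if (nd < dist[vl]) dist[vl] <- nd
      }
      if (all(done)) break
    }
    upd <- dist < best
    best[upd] <- dist[upd]
    label[upd] <- s
  }
  label[!as.vector(foreground)] <- 0L
  array(label, dim = d)
}

# Independent per-voxel accumulation of segment sums/counts (plain loop).
oracle_brightness <- function(values, labels) {
  L <- max(labels)
  sums <- numeric(L)
  counts <- integer(L)
  for (i in seq_along(values)) {
    l <- labels[i]
    if (l == 0) next
    sums[l] <- sums[l] + values[i]
    counts[l] <- counts[l] + 1L
  }
  ids <- which(counts > 0L)
  data.frame(spot_id = ids,
             mean_brightness = sums[ids] / counts[ids],
             voxel_count = counts[ids])
}

# Wrap a raw array as a normalized grid (isotropic spacing s).
norm_grid <- function(arr, s = 0.2) {
  normalize_intensity(voxel_grid(arr, spacing_um = rep(s, 3)))
}

# Build a seed_set by hand from a matrix of 1-based (z, y, x) indices.
make_seed_set <- function(grid, seeds) {
  seeds <- matrix(as.integer(seeds), ncol = 3,
                  dimnames = list(NULL, c("z", "y", "x")))
  ints <- grid$data[seeds]
  structure(list(seeds = seeds, intensities = ints), class = "seed_set")
}

# Small anisotropic test scene (z-step 1 um, lateral 0.2 um).
small_scene <- function(n_spots = 4, seed = 1, noise = "none",
                        shape = c(6, 32, 32), amplitude = c(80, 120),
                        sigma = c(0.25, 0.35)) {
  np <- switch(noise,
               none = list(sd = 0),
               gaussian = list(sd = 4),
               pg = list(gain = 2, read_sd = 5))
  scene_spec(shape_voxels = shape, voxel_spacing_um = c(1.0, 0.2, 0.2),
             n_spots = n_spots, amplitude_range = amplitude,
             sigma_um_range = sigma, min_separation_um = 2.0,
             background_level = 10,
             noise_model = if (noise == "pg") "poisson-gaussian" else "gaussian",
             noise_params = np, rng_seed = seed)
}

# Greedy matching of true centres (um) to detected seed positions (um);
# returns per-spot distance of the nearest detected seed.
match_seed_distances <- function(centers_um, seed_pos_um) {
  if (nrow(seed_pos_um) == 0L) return(rep(Inf, nrow(centers_um)))
  vapply(seq_len(nrow(centers_um)), function(i) {
    min(sqrt(rowSums((seed_pos_um -
      matrix(centers_um[i, ], nrow(seed_pos_um), 3, byrow = TRUE))^2)))
  }, 0)
}

iou <- function(a, b) {
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  i / u
}

# Random single-indel mutant of a sequence; returns the mutant and the
# generating edit for round-trip checks.
random_indel_mutant <- function(wt) {
  n <- nchar(wt)
  kind <- sample(c("deletion", "insertion"), 1)
  if (kind == "deletion") {
    len <- sample(1:min(8, n - 2), 1)
    pos <- sample(1:(n - len), 1)
    mut <- paste0(substr(wt, 1, pos - 1), substr(wt, pos + len, n))
  } else {
    len <- sample(1:8, 1)
    pos <- sample(1:(n + 1), 1)
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    mut <- paste0(substr(wt, 1, pos - 1), ins, substr(wt, pos, n))
  }
  list(kind = kind, mut = mut)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
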