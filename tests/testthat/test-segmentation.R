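test_that("a flat field yields no seeds", {
  g <- norm_grid(array(4, dim = c(6, 6, 6)))
  s <- detect_seeds(g, h_min = 0.1)
  expect_identical(nrow(s$seeds), 0L)
})

test_that("well-separated gaussian spots seed exactly once each", {
  sp <- small_scene(n_spots = 5, seed = 14, noise = "none",
                    shape = c(8, 40, 40))
  st <- generate_stack(sp)
  g <- normalize_intensity(
    smooth_gaussian(resample_isotropic(st$grid, 0.2), 0.2))
  s <- detect_seeds(g, h_min = 0.2, min_separation_um = 0.6)
  expect_identical(nrow(s$seeds), 5L)
  pos_um <- (s$seeds - 1) * rep(g$spacing_um, each = nrow(s$seeds))
  dists <- match_seed_distances(st$ground_truth$centers_um, pos_um)
  expect_true(all(dists <= 0.2 * sqrt(3)))
  # seed intensities are the grid values at the seed voxels
  expect_equal(s$intensities, g$data[s$seeds])
})

test_that("seed detection is equivariant under whole-voxel translation", {
  base <- array(1, dim = c(12, 12, 12))
  gauss <- function(ctr) {
    a <- base
    for (z in 1:12) for (y in 1:12) for (x in 1:12)
      a[z, y, x] <- 1 + 50 * exp(-sum((c(z, y, x) - ctr)^2) / (2 * 1.5^2))
    a
  }
  s1 <- detect_seeds(norm_grid(gauss(c(5, 6, 5))), h_min = 0.5)
  s2 <- detect_seeds(norm_grid(gauss(c(7, 8, 6))), h_min = 0.5)
  expect_identical(nrow(s1$seeds), 1L)
  expect_identical(s2$seeds - s1$seeds, matrix(c(2L, 2L, 1L), 1,
                   dimnames = list(NULL, c("z", "y", "x"))))
})

test_that("plateau maxima give one centroid seed; shoulders give none", {
  a <- array(0, dim = c(5, 9, 9))
  a[3, 4:5, 4:5] <- 2   # 2x2 plateau
  s <- detect_seeds(norm_grid(a), h_min = 0.1)
  expect_identical(nrow(s$seeds), 1L)
  expect_true(s$seeds[1, "y"] %in% 4:5 && s$seeds[1, "x"] %in% 4:5)

  # a flat ledge adjacent to a brighter ridge is not a maximum
  b <- array(0, dim = c(3, 5, 8))
  b[2, 3, 1:4] <- 5      # ledge
  b[2, 3, 5] <- 9        # brighter neighbour
  sb <- detect_seeds(norm_grid(b), h_min = 0.1)
  expect_identical(nrow(sb$seeds), 1L)
  expect_identical(as.integer(sb$seeds[1, ]), c(2L, 3L, 5L))
})

test_that("single-seed segmentation labels the whole connected foreground", {
  a <- array(0.05, dim = c(6, 10, 10))
  a[3, 4:7, 4:7] <- c(0.5, 0.6, 0.7, 0.8)
  g <- norm_grid(a)
  seeds <- make_seed_set(g, which(g$data == max(g$data), arr.ind = TRUE)[1, ])
  lab <- segment_spots(g, seeds, foreground_threshold = 0.3)
  expect_identical(lab$n_spots, 1L)
  expect_true(all(lab$labels[g$data >= 0.3] == 1L))
  expect_true(all(lab$labels[g$data < 0.3] == 0L))
})

test_that("mirror-symmetric twin spots split on the mid-plane", {
  d <- c(7, 7, 16)
  a <- array(0, dim = d)
  for (z in 1:7) for (y in 1:7) for (x in 1:16) {
    a[z, y, x] <- 100 * exp(-sum((c(z, y, x) - c(4, 4, 5))^2) / (2 * 2^2)) +
                  100 * exp(-sum((c(z, y, x) - c(4, 4, 12))^2) / (2 * 2^2))
  }
  g <- norm_grid(a)
  seeds <- make_seed_set(g, rbind(c(4, 4, 5), c(4, 4, 12)))
  lab <- segment_spots(g, seeds, foreground_threshold = 0.2)
  lx <- lab$labels
  expect_true(all(lx[, , 1:8][lx[, , 1:8] > 0] == 1L))
  expect_true(all(lx[, , 9:16][lx[, , 9:16] > 0] == 2L))
})

test_that("labels match the exhaustive per-seed Dijkstra oracle exactly", {
  set.seed(77)
  for (case in 1:6) {
    d <- c(sample(8:12, 1), sample(8:12, 1), sample(8:12, 1))
    n_seed <- sample(2:4, 1)
    a <- array(0.1, dim = d)
    # smooth random field: a few random gaussian bumps
    for (b in seq_len(n_seed + 1)) {
      ctr <- c(runif(1, 1, d[1]), runif(1, 1, d[2]), runif(1, 1, d[3]))
      amp <- runif(1, 0.3, 1)
      sg <- runif(1, 1, 2.5)
      for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
        a[z, y, x] <- a[z, y, x] +
          amp * exp(-sum((c(z, y, x) - ctr)^2) / (2 * sg^2))
    }
    g <- norm_grid(a)
    thr <- quantile(g$data, 0.3)
    fg <- g$data >= thr
    fg_idx <- which(fg, arr.ind = TRUE)
    seeds <- make_seed_set(g, fg_idx[sample(nrow(fg_idx), n_seed), ])
    lab <- segment_spots(g, seeds, foreground_threshold = thr, lambda = 5)
    orc <- oracle_labels(g$data, fg, seeds$seeds, lambda = 5)
    expect_identical(lab$labels, orc)
  }

  # tie-break case: flat foreground, equal costs everywhere -> smaller seed
  # index wins on the equidistant plane, identically in both routes
  flat <- norm_grid(array(1, dim = c(5, 5, 9)) +
                      array(rep(0, 225), dim = c(5, 5, 9)))
  seeds <- make_seed_set(flat, rbind(c(3, 3, 3), c(3, 3, 7)))
  lab <- segment_spots(flat, seeds, foreground_threshold = 0, lambda = 5)
  orc <- oracle_labels(flat$data, array(TRUE, dim(flat$data)), seeds$seeds, 5)
  expect_identical(lab$labels, orc)
  expect_true(all(lab$labels[, , 5] == 1L)) # exact mid-plane tie -> seed 1
})

test_that("connectedness follows the 26-neighbourhood path definition", {
  lab <- array(0L, dim = c(3, 5, 5))
  lab[2, 2, 2] <- 1L                       # single voxel
  lab[1, 4, 4] <- 2L; lab[2, 5, 5] <- 2L   # diagonal touch (26-adjacent)
  lab[3, 1, 1] <- 3L; lab[3, 1, 3] <- 3L   # gap of one background voxel
  m <- punctaseg:::new_spot_label_map(lab, 3L, 0.5)
  expect_true(check_connected(m, 1))
  expect_true(check_connected(m, 2))
  expect_false(check_connected(m, 3))
  expect_error(check_connected(m, 9), "absent")
})

test_that("every emitted segment is connected and the partition is exact", {
  for (seed in 1:10) {
    st <- generate_stack(small_scene(n_spots = 4, seed = seed, noise = "pg"))
    res <- run_image_pipeline(list(s = st$grid), config = pipeline_config())
    lab <- res$label_maps[[1]]
    if (lab$n_spots == 0) next
    present <- setdiff(sort(unique(as.integer(lab$labels))), 0L)
    for (l in present) expect_true(check_connected(lab, l))
    # partition identity on the segmentation grid
    seg_total <- sum(tabulate(as.integer(lab$labels)[lab$labels > 0]))
    expect_identical(seg_total + lab$unreachable, lab$n_foreground)
  }
})

test_that("segmentation is invariant to pre-normalization intensity scaling", {
  st <- generate_stack(small_scene(n_spots = 3, seed = 4, noise = "gaussian"))
  go <- smooth_gaussian(resample_isotropic(st$grid, 0.2), 0.2)
  gk <- voxel_grid(go$data * 7.3, go$spacing_um)
  n1 <- normalize_intensity(go)
  n2 <- normalize_intensity(gk)
  s1 <- detect_seeds(n1, 0.15, 0.6)
  s2 <- detect_seeds(n2, 0.15, 0.6)
  expect_identical(s1$seeds, s2$seeds)
  keep <- s1$intensities >= 0.2
  s1$seeds <- s1$seeds[keep, , drop = FALSE]
  s1$intensities <- s1$intensities[keep]
  s2$seeds <- s2$seeds[keep, , drop = FALSE]
  s2$intensities <- s2$intensities[keep]
  l1 <- segment_spots(n1, s1, foreground_threshold = 0.2)
  l2 <- segment_spots(n2, s2, foreground_threshold = 0.2)
  expect_identical(l1$labels, l2$labels)
})

test_that("segmentation preconditions are enforced", {
  a <- array(0.1, dim = c(4, 4, 4)); a[2, 2, 2] <- 1
  g <- norm_grid(a)
  seeds <- make_seed_set(g, matrix(c(1, 1, 1), 1)) # dim corner voxel
  expect_error(segment_spots(g, seeds, foreground_threshold = 0.5),
               "below the foreground threshold")
  empty <- structure(list(seeds = matrix(integer(), 0, 3),
                          intensities = numeric()), class = "seed_set")
  expect_error(segment_spots(g, empty, foreground_threshold = 0.5),
               "empty seed set")
})
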