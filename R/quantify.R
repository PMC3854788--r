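#' Per-spot mean brightness
#'
#' For every segment `S_l` of a label map, computes the average brightness
#' `mean = sum(I(x), x in S_l) / |S_l|`, i.e. the summed normalized
#' intensity over the segment divided by the segment's volume in voxels.
#' The physical volume (`voxel_count * prod(spacing)`) is reported
#' separately, so a per-um^3 variant is a constant rescale.
#'
#' @param grid a normalized [voxel_grid()] sharing shape and spacing with
#'   `labels`.
#' @param labels a `spot_label_map`.
#' @param seeds optional `seed_set` whose i-th seed generated segment i;
#'   seed positions are then reported in physical um.
#' @return a data frame, one row per segment, sorted by `spot_id`, with
#'   columns `spot_id`, `voxel_count`, `volume_um3`, `sum_brightness`,
#'   `mean_brightness`, `seed_z_um`, `seed_y_um`, `seed_x_um`.
#' @export
spot_brightness <- function(grid, labels, seeds = NULL) {
  stopifnot_grid(grid)
  if (!inherits(labels, "spot_label_map")) stop("expected a `spot_label_map`")
  if (!identical(dim(grid$data), dim(labels$labels)))
    stop("grid and label map shapes differ")
  lab <- as.integer(labels$labels)
  sel <- lab > 0L
  ids <- sort(unique(lab[sel]))
  f <- factor(lab[sel], levels = ids)
  sums <- vapply(split(as.numeric(grid$data)[sel], f), sum, 0)
  counts <- vapply(split(lab[sel], f), length, 0L)
  vox_vol <- prod(grid$spacing_um)
  pos <- matrix(NA_real_, length(ids), 3)
  if (!is.null(seeds)) {
    if (nrow(seeds$seeds) < max(c(0L, ids)))
      stop("seed set has fewer seeds than the label map has segments")
    pos <- (seeds$seeds[ids, , drop = FALSE] - 1) *
      rep(grid$spacing_um, each = length(ids))
  }
  data.frame(spot_id = ids,
             voxel_count = as.integer(counts),
             volume_um3 = counts * vox_vol,
             sum_brightness = as.numeric(sums),
             mean_brightness = as.numeric(sums) / counts,
             seed_z_um = pos[, 1], seed_y_um = pos[, 2], seed_x_um = pos[, 3],
             row.names = NULL)
}

#' Summarize spot brightness for one experimental group
#'
#' Pools the per-spot mean brightness of all records in a group (across
#' stacks when a `stack_id` column is present) and reports their mean and
#' sample standard deviation (`n - 1` denominator) — the per-group
#' "mean +/- SD across spots" statistic. The SD is across spots, not across
#' voxels; with a single spot it is `NA`.
#'
#' @param records a data frame of spot records (see [spot_brightness()]),
#'   optionally carrying a `stack_id` column.
#' @param group_name label for the group.
#' @return a list of class `group_summary` with `group_name`, `n_spots`,
#'   `mean_of_spot_brightness`, `sd_of_spot_brightness`, `stacks_included`.
#' @export
summarize_group <- function(records, group_name = "group") {
  if (is.null(records) || nrow(records) == 0L) stop("no spots")
  b <- records$mean_brightness
  structure(list(group_name = group_name,
                 n_spots = length(b),
                 mean_of_spot_brightness = mean(b),
                 sd_of_spot_brightness = if (length(b) >= 2L)
                   stats::sd(b) else NA_real_,
                 stacks_included = if (!is.null(records$stack_id))
                   unique(records$stack_id) else character()),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d spots, brightness %.4f +/- %s\n",
              x$group_name, x$n_spots, x$mean_of_spot_brightness,
              if (is.na(x$sd_of_spot_brightness)) "NA"
              else sprintf("%.4f", x$sd_of_spot_brightness)))
  invisible(x)
}

#' Brightness fold change between two groups
#'
#' Ratio of the reference group's mean spot brightness to the comparison
#' group's, e.g. wild-type over mutant; a value of 2 means a two-fold
#' reduction in the comparison group. Meaningful only when both groups were
#' normalized by a common (cohort) constant.
#'
#' @param reference,comparison `group_summary` objects.
#' @return a scalar fold change.
#' @export
fold_change <- function(reference, comparison) {
  for (g in list(reference, comparison))
    if (!inherits(g, "group_summary")) stop("expected `group_summary` objects")
  if (!is.finite(comparison$mean_of_spot_brightness) ||
      comparison$mean_of_spot_brightness <= 0)
    stop("comparison group has non-positive mean brightness")
  reference$mean_of_spot_brightness / comparison$mean_of_spot_brightness
}
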