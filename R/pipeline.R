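#' Image pipeline configuration
#'
#' Collects every tunable of the stack-to-statistics workflow. Defaults are
#' recorded in the run manifest even when unset by the user.
#'
#' @param preprocess a [preprocess_config()].
#' @param h_min minimal seed intensity on the normalized enhanced grid.
#' @param min_separation_um seed merge radius, um.
#' @param fg_threshold foreground threshold on the normalized enhanced grid;
#'   `NULL` selects [robust_fg_threshold()] per stack.
#' @param lambda intensity weighting of the front-propagation traversal cost.
#' @param normalize `"cohort"` (one common constant across all stacks of a
#'   comparison; required for between-group fold changes) or `"per-stack"`.
#' @param background_percentile percentile of the smoothed intensity taken
#'   as the diffuse background on the quantification path. The default, the
#'   median, estimates the background level essentially unbiasedly in
#'   background-dominated stacks (puncta occupy a small volume fraction),
#'   whereas a tail percentile would land several noise SDs below it and
#'   leave a residual offset that biases fold changes toward 1.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            h_min = 0.1,
                            min_separation_um = 0.4,
                            fg_threshold = NULL,
                            lambda = 5,
                            normalize = c("cohort", "per-stack"),
                            background_percentile = 50) {
  normalize <- match.arg(normalize)
  structure(list(preprocess = preprocess, h_min = h_min,
                 min_separation_um = min_separation_um,
                 fg_threshold = fg_threshold, lambda = lambda,
                 normalize = normalize,
                 background_percentile = background_percentile),
            class = "pipeline_config")
}

#' Run the full image analysis pipeline
#'
#' Executes, for every stack: isotropic resampling, Gaussian smoothing,
#' contrast and Laplacian enhancement, seed detection, geodesic spot
#' segmentation, and per-spot mean brightness; then summarizes each group
#' (mean and SD of spot brightness) and, when exactly two groups are given,
#' their fold change.
#'
#' Segmentation runs on the enhanced, per-stack-normalized grid (contrast
#' enhancement helps seeding but its percentile clipping is not
#' photometrically linear). Brightness is measured on the linear grid
#' (resampled + smoothed) after background subtraction, normalized either by
#' a single cohort-wide maximum (default; preserves between-group intensity
#' ratios, required for fold changes) or per stack.
#'
#' @param stacks named list of [voxel_grid()] objects, or of file paths
#'   readable by [read_stack()].
#' @param groups character vector assigning each stack to a group; `NULL`
#'   puts all stacks in one group.
#' @param config a [pipeline_config()].
#' @param reference group name used as fold-change numerator (default:
#'   first group).
#' @param out_dir optional directory; per-spot CSV, group-summary JSON and
#'   the run manifest are written there.
#' @param spacing_um fallback voxel spacing for stacks given as paths
#'   without sidecar metadata.
#' @return a list with `records` (per-spot data frame across stacks),
#'   `summaries` (list of `group_summary`), `per_stack_means`,
#'   `fold_change` (or `NULL`), `label_maps`, and `manifest`.
#' @export
run_image_pipeline <- function(stacks, groups = NULL,
                               config = pipeline_config(),
                               reference = NULL, out_dir = NULL,
                               spacing_um = NULL) {
  if (!length(stacks)) stop("no stacks given")
  if (is.null(names(stacks)))
    names(stacks) <- sprintf("stack%02d", seq_along(stacks))
  checksums <- rep(NA_character_, length(stacks))
  for (i in seq_along(stacks)) {
    if (is.character(stacks[[i]])) {
      checksums[i] <- unname(tools::md5sum(stacks[[i]]))
      stacks[[i]] <- read_stack(stacks[[i]], spacing_um = spacing_um)
    }
    stopifnot_grid(stacks[[i]])
  }
  if (is.null(groups)) groups <- rep("all", length(stacks))
  if (length(groups) != length(stacks))
    stop("`groups` must name one group per stack")

  pp <- config$preprocess
  linear <- lapply(stacks, function(g)
    smooth_gaussian(resample_isotropic(g, pp$target_spacing_um),
                    pp$gaussian_sigma_um))

  # quantification path: background-subtracted linear intensities
  bg <- if (config$normalize == "cohort")
    stats::quantile(unlist(lapply(linear, function(g) as.numeric(g$data))),
                    config$background_percentile / 100, names = FALSE)
  else NA_real_
  meas <- lapply(linear, function(g) {
    b <- if (config$normalize == "cohort") bg
         else stats::quantile(g$data, config$background_percentile / 100,
                              names = FALSE)
    voxel_grid(pmax(g$data - b, 0), g$spacing_um, g$origin_um)
  })
  norm_const <- if (config$normalize == "cohort")
    max(vapply(meas, function(g) max(g$data), 0))
  else NA_real_
  meas <- lapply(meas, function(g) {
    mx <- if (config$normalize == "cohort") norm_const else max(g$data)
    if (!is.finite(mx) || mx <= 0) {
      # flat stack: nothing above background, leave the zeros in place
      g$normalized <- TRUE
      g
    } else normalize_intensity(g, max_value = mx)
  })

  # segmentation path: enhanced, per-stack normalized
  records <- NULL
  label_maps <- vector("list", length(stacks))
  names(label_maps) <- names(stacks)
  thresholds <- numeric(length(stacks))
  for (i in seq_along(stacks)) {
    enh <- normalize_intensity(
      enhance_laplacian(
        enhance_histogram(linear[[i]], pp$histogram_stretch_percentiles),
        pp$laplacian_weight))
    seeds <- detect_seeds(enh, config$h_min, config$min_separation_um)
    thr <- if (is.null(config$fg_threshold)) robust_fg_threshold(enh)
           else config$fg_threshold
    thresholds[i] <- thr
    # dim maxima below the foreground cut cannot generate a segment
    keep <- seeds$intensities >= thr
    if (any(!keep))
      message("stack ", names(stacks)[i], ": dropping ", sum(!keep),
              " sub-threshold seed(s)")
    seeds$seeds <- seeds$seeds[keep, , drop = FALSE]
    seeds$intensities <- seeds$intensities[keep]
    if (nrow(seeds$seeds) == 0L) {
      warning("stack ", names(stacks)[i], ": no seeds detected")
      label_maps[[i]] <- new_spot_label_map(
        array(0L, dim = dim(enh$data)), 0L, thr)
      next
    }
    labs <- segment_spots(enh, seeds, foreground_threshold = thr,
                          lambda = config$lambda)
    label_maps[[i]] <- labs
    rec <- spot_brightness(meas[[i]], labs, seeds = seeds)
    if (nrow(rec)) {
      rec <- cbind(stack_id = names(stacks)[i], group = groups[i], rec)
      records <- rbind(records, rec)
    }
  }

  summaries <- list()
  for (g in unique(groups)) {
    rg <- records[records$group == g, , drop = FALSE]
    if (is.null(rg) || nrow(rg) == 0L) {
      warning("group ", g, ": no spots detected")
      summaries[[g]] <- structure(list(group_name = g, n_spots = 0L,
                                       mean_of_spot_brightness = NA_real_,
                                       sd_of_spot_brightness = NA_real_,
                                       stacks_included = names(stacks)[groups == g]),
                                  class = "group_summary")
    } else summaries[[g]] <- summarize_group(rg, g)
  }
  per_stack_means <- if (!is.null(records))
    stats::aggregate(mean_brightness ~ stack_id + group, records, mean)
  else data.frame()

  fc <- NULL
  if (length(summaries) == 2L) {
    if (is.null(reference)) reference <- unique(groups)[1]
    other <- setdiff(names(summaries), reference)
    if (length(other) == 1L &&
        isTRUE(summaries[[other]]$mean_of_spot_brightness > 0))
      fc <- fold_change(summaries[[reference]], summaries[[other]])
  }

  manifest <- list(
    tool = "punctaseg",
    version = as.character(utils::packageVersion("punctaseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stacks = names(stacks), groups = groups, checksums = checksums,
    config = list(
      target_spacing_um = pp$target_spacing_um,
      gaussian_sigma_um = pp$gaussian_sigma_um,
      histogram_stretch_percentiles = pp$histogram_stretch_percentiles,
      laplacian_weight = pp$laplacian_weight,
      h_min = config$h_min,
      min_separation_um = config$min_separation_um,
      fg_threshold = if (is.null(config$fg_threshold)) "otsu"
                     else config$fg_threshold,
      lambda = config$lambda,
      normalize = config$normalize,
      background_percentile = config$background_percentile),
    fg_thresholds_used = thresholds,
    background_subtracted = bg,
    normalization_constant = norm_const,
    reference = if (!is.null(fc)) reference else NA)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(if (is.null(records)) data.frame() else records,
                     file.path(out_dir, "spots.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(summaries, unclass),
      file.path(out_dir, "group_summaries.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, summaries = summaries,
       per_stack_means = per_stack_means, fold_change = fc,
       label_maps = label_maps, manifest = manifest)
}

#' Run the allele-consequence pipeline
#'
#' Calls the indel of every mutant record in a FASTA against the configured
#' wild-type record and derives the protein consequence, reproducing an
#' allele characterization table (one row per mutant).
#'
#' @param fasta path to a FASTA with one wild-type record and zero or more
#'   mutant records; alternatively pass `sequences`, a named character
#'   vector.
#' @param sequences named character vector of sequences (used when `fasta`
#'   is `NULL`).
#' @param region a [target_region()] for the wild-type record; defaults to
#'   the packaged kif7 region when the wild-type sequence matches it.
#' @param wild_type_name name of the wild-type record.
#' @param policy indel placement policy, see [call_indel()].
#' @param out_tsv optional path for a TSV of the table.
#' @return a data frame with columns `allele`, `kind`, `position_nt`,
#'   `length_nt`, `ref_allele`, `notation`, `mutant_peptide`, plus a
#'   `manifest` attribute. Records that are not a single contiguous indel
#'   get `kind = "complex"` and a warning.
#' @examples
#' fx <- kif7_allele_fixtures()
#' run_allele_pipeline(sequences = fx$sequences, region = fx$region)
#' @export
run_allele_pipeline <- function(fasta = NULL, sequences = NULL, region = NULL,
                                wild_type_name = "wild-type",
                                policy = "leftmost", out_tsv = NULL) {
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    sequences <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(sequences)) stop("supply `fasta` or `sequences`")
  if (!wild_type_name %in% names(sequences))
    stop("wild-type record '", wild_type_name, "' missing from input")
  wt <- sequences[[wild_type_name]]
  if (is.null(region)) {
    fx <- kif7_allele_fixtures()
    if (!identical(toupper(wt), fx$region$sequence))
      stop("no `region` given and the wild-type record is not the packaged ",
           "kif7 target region")
    region <- fx$region
  }
  mut_names <- setdiff(names(sequences), wild_type_name)
  rows <- lapply(mut_names, function(nm) {
    res <- tryCatch({
      ind <- call_indel(region, sequences[[nm]], policy = policy)
      pc <- protein_consequence(region, ind, sequences[[nm]])
      data.frame(allele = nm, kind = ind$kind,
                 position_nt = ind$position_nt, length_nt = ind$length_nt,
                 ref_allele = ind$ref_allele, notation = pc$notation,
                 mutant_peptide = pc$mutant_peptide)
    }, error = function(e) {
      kind <- if (grepl("^no variant", conditionMessage(e))) "none"
              else "complex"
      if (kind == "complex")
        warning("allele ", nm, ": ", conditionMessage(e), call. = FALSE)
      data.frame(allele = nm, kind = kind, position_nt = NA_integer_,
                 length_nt = NA_integer_, ref_allele = NA_character_,
                 notation = NA_character_, mutant_peptide = NA_character_)
    })
    res
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(allele = character(), kind = character(),
               position_nt = integer(), length_nt = integer(),
               ref_allele = character(), notation = character(),
               mutant_peptide = character())
  attr(tab, "manifest") <- list(
    tool = "punctaseg",
    version = as.character(utils::packageVersion("punctaseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    wild_type = wild_type_name, policy = policy,
    cds_start_nt = region$cds_start_nt, frame_offset = region$frame_offset,
    first_residue_number = region$first_residue_number)
  if (!is.null(out_tsv))
    utils::write.table(tab, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
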