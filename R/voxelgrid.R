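#' Construct a voxel grid
#'
#' A `voxel_grid` is the package's container for a 3D scalar fluorescence
#' field: a numeric array in `(z, y, x)` index order together with the
#' physical voxel spacing in micrometres. Physical positions refer to voxel
#' centres; the centre of voxel `(1, 1, 1)` sits at `origin_um`
#' (default `(0, 0, 0)`).
#'
#' @param data numeric 3D array, indexed `(z, y, x)`.
#' @param spacing_um positive numeric length-3, voxel spacing `(z, y, x)` in um.
#' @param origin_um numeric length-3, physical position of the first voxel
#'   centre in um.
#' @param normalized logical; `TRUE` once intensities have been scaled to
#'   `[0, 1]` with maximum 1 (see [normalize_intensity()]).
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(runif(4 * 5 * 6), dim = c(4, 5, 6)),
#'                 spacing_um = c(1, 0.2, 0.2))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing_um, origin_um = c(0, 0, 0),
                       normalized = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("`spacing_um` must be three positive values (z, y, x)")
  structure(
    list(data = data, spacing_um = spacing_um,
         origin_um = as.numeric(origin_um), normalized = isTRUE(normalized)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), spacing %s um%s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_um), collapse = " x "),
              if (x$normalized) ", normalized" else ""))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "voxel_grid")) stop("expected a `voxel_grid`")
  invisible(grid)
}

#' Read a 3D stack from a multi-page TIFF
#'
#' Pages of the TIFF are stacked along z. Voxel spacing is taken from a
#' sidecar metadata file (`<stem>.meta`, `key=value` lines with a
#' `spacing_um` entry `z,y,x`) when present, otherwise it must be supplied.
#'
#' @param path path to a multi-page TIFF written by [write_stack()] or any
#'   greyscale multi-page TIFF.
#' @param spacing_um optional numeric length-3 `(z, y, x)` in um; overrides
#'   the sidecar.
#' @return a [voxel_grid()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), ny, nx))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  meta_path <- paste0(tools::file_path_sans_ext(path), ".meta")
  if (file.exists(meta_path)) {
    meta <- read_keyvalue(meta_path)
    if (is.null(spacing_um) && !is.null(meta$spacing_um))
      spacing_um <- as.numeric(strsplit(meta$spacing_um, ",")[[1]])
    if (!is.null(meta$intensity_scale))
      arr <- arr * as.numeric(meta$intensity_scale)
    if (!is.null(meta$intensity_offset))
      arr <- arr + as.numeric(meta$intensity_offset)
  }
  if (is.null(spacing_um))
    stop("voxel spacing not found: supply `spacing_um` or a sidecar .meta file")
  voxel_grid(arr, spacing_um = spacing_um)
}

#' Write a 3D stack as a multi-page TIFF plus metadata sidecar
#'
#' Intensities are rescaled to `[0, 1]` for storage (TIFF float pages);
#' the scale factor and the voxel spacing are recorded in a `key=value`
#' sidecar file next to the image so [read_stack()] can restore spacing.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot_grid(grid)
  # TIFF float pages must lie in [0, 1]; store an affine-mapped copy and
  # record the map in the sidecar so read_stack() can undo it
  rng <- range(grid$data)
  offset <- rng[1]
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(dim(grid$data)[1]),
                  function(z) (grid$data[z, , ] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta_path <- paste0(tools::file_path_sans_ext(path), ".meta")
  writeLines(c(
    sprintf("spacing_um=%s", paste(format(grid$spacing_um, digits = 17),
                                   collapse = ",")),
    sprintf("intensity_offset=%s", format(offset, digits = 17)),
    sprintf("intensity_scale=%s", format(scale, digits = 17)),
    sprintf("normalized=%s", grid$normalized)
  ), meta_path)
  invisible(path)
}

#' Write a spot label map as a 16-bit TIFF
#'
#' @param labels a `spot_label_map` (see [segment_spots()]).
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (!inherits(labels, "spot_label_map")) stop("expected a `spot_label_map`")
  if (labels$n_spots > 65535L) stop("more than 65535 labels")
  pages <- lapply(seq_len(dim(labels$labels)[1]),
                  function(z) labels$labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad)) stop("malformed key=value line: ", lines[bad][1])
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(out) <- vapply(kv, function(p) trimws(p[1]), "")
  out
}
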