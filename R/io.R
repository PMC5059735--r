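## image_io: TIFF raster I/O, channel binding, tabular output.
##
## Images are plain multi-plane TIFFs (uint8/uint16), one plane per channel;
## channel order is never guessed — it comes from the channel map. Pixel
## intensities are handled as integer photon counts throughout; on disk they
## are stored as uint16.

MAXCOUNT <- 65535

particleCols <- c("image", "condition", "cell_id", "particle_id", "area_px",
                  "perimeter_px", "major_axis_px", "minor_axis_px",
                  "aspect_ratio", "circularity", "centroid_row",
                  "centroid_col")
cellCols <- c("image", "condition", "cell_id", "n_particles",
              "mean_circularity", "mean_aspect_ratio", "total_mito_area_px")
conditionCols <- c("condition", "n_cells", "mean_circularity",
                   "sd_circularity", "mean_aspect_ratio", "sd_aspect_ratio")

readTiffPlanes <- function(path) {
  if (!file.exists(path))
    stopc("mitomorph_error_missing_file", "file not found: %s", path)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  lapply(planes, function(p) {
    bps <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1]
      else stopc("mitomorph_error_bad_image",
                 "multi-sample (colour) TIFF planes are not supported: %s",
                 path)
    }
    ## integer samples come back scaled to [0, 1]; restore the raw counts.
    ## 32-bit planes are floating point and are kept as stored.
    if (!is.null(bps) && bps %in% c(1L, 8L, 16L)) p <- round(p * (2^bps - 1))
    p <- matrix(as.double(p), nrow(p), ncol(p))
    p
  })
}

#' Load a multi-plane TIFF and bind planes to channel roles
#'
#' Reads a single-position multi-plane TIFF and maps planes to the semantic
#' roles \code{nucleus}, \code{membrane}, \code{mito} using an explicit
#' channel map; no positional defaults are applied when a map is given.
#' Pixel size comes from the caller (configuration), never from TIFF
#' metadata.
#'
#' @param path TIFF file path.
#' @param channel_map named list/vector of 1-based plane indices, names
#'   among \code{nucleus}, \code{membrane}, \code{mito}. All named roles are
#'   bound; at minimum \code{mito} must be present.
#' @param pixel_size_um physical pixel size in micrometers (default 0.2).
#' @return A \linkS4class{MultiChannelImage}.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' planes <- list(matrix(0L, 8, 8), matrix(1L, 8, 8), matrix(2L, 8, 8))
#' writeStack(MultiChannelImage(list(nucleus = planes[[1]],
#'   membrane = planes[[2]], mito = planes[[3]])), tf)
#' img <- loadStack(tf, list(nucleus = 1, membrane = 2, mito = 3))
#' channelRoles(img)
loadStack <- function(path, channel_map, pixel_size_um = 0.2) {
  planes <- readTiffPlanes(path)
  idx <- unlist(channel_map)
  roles <- names(idx)
  allowed <- c("nucleus", "membrane", "mito")
  if (is.null(roles) || any(!roles %in% allowed))
    stopc("mitomorph_error_bad_channel_map",
          "channel map roles must be among: %s", paste(allowed, collapse = ", "))
  if (anyDuplicated(roles) || anyDuplicated(idx))
    stopc("mitomorph_error_duplicate_role",
          "duplicate role or plane index in channel map")
  if (any(idx < 1L) || any(idx > length(planes)))
    stopc("mitomorph_error_plane_index",
          "channel map requests plane outside 1..%d", length(planes))
  bound <- stats::setNames(planes[idx], roles)
  MultiChannelImage(bound, pixelSize = pixel_size_um, sourcePath = path)
}

#' Write a MultiChannelImage as a multi-plane uint16 TIFF
#'
#' Planes are written in the order nucleus, membrane, mito (those present).
#' Intensities are rounded and clamped to 0..65535; reading back with
#' [loadStack()] is pixel-identical for integer-valued images.
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(img, path) {
  stopifnot(is(img, "MultiChannelImage"))
  order <- intersect(c("nucleus", "membrane", "mito"), channelRoles(img))
  planes <- lapply(img@planes[order], function(p)
    round(clampRange(p, 0, MAXCOUNT)) / MAXCOUNT)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Load a cell-label mask (semi-manual mode input)
#'
#' Reads a single-plane integer-valued TIFF as a cell label image, the
#' interchange format for manually delimited cell outlines (label 0 =
#' background). Float-valued images are rejected; an all-zero mask is
#' accepted with a warning.
#'
#' @param path TIFF file path.
#' @return A \linkS4class{LabelImage} of kind \code{"cells"}.
#' @export
loadLabelMask <- function(path) {
  planes <- readTiffPlanes(path)
  if (length(planes) != 1L)
    stopc("mitomorph_error_bad_image",
          "label mask must be a single-plane TIFF (%d planes found)",
          length(planes))
  m <- planes[[1]]
  if (!isWholeNumber(m))
    stopc("mitomorph_error_float_mask",
          "label mask contains non-integer pixel values")
  if (all(m == 0))
    warnc("mitomorph_warning_empty_mask", "label mask is all zero (no cells)")
  LabelImage(m, kind = "cells")
}

#' Write a LabelImage as a uint16 TIFF
#'
#' @param lab a \linkS4class{LabelImage} with labels below 65536.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(lab, path) {
  stopifnot(is(lab, "LabelImage"))
  m <- lab@labels
  if (max(m) > MAXCOUNT)
    stopc("mitomorph_error_bad_image", "labels exceed uint16 range")
  tiff::writeTIFF(m / MAXCOUNT, path, bits.per.sample = 16L)
  invisible(path)
}

fmtNum <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  df
}

padCols <- function(df, cols) {
  for (nm in setdiff(cols, names(df)))
    df[[nm]] <- if (nrow(df)) NA else character(0)
  df[, cols, drop = FALSE]
}

#' Write the per-particle, per-cell and per-condition CSV tables
#'
#' Writes \code{particles.csv}, \code{cells.csv} and \code{conditions.csv}
#' with fixed, documented column orders (see Details). Floating-point
#' values are written at 6 significant digits. Missing bookkeeping columns
#' (\code{image}, \code{condition}) are padded with \code{NA}.
#'
#' @details Column orders: particles — image, condition, cell_id,
#'   particle_id, area_px, perimeter_px, major_axis_px, minor_axis_px,
#'   aspect_ratio, circularity, centroid_row, centroid_col; cells — image,
#'   condition, cell_id, n_particles, mean_circularity, mean_aspect_ratio,
#'   total_mito_area_px; conditions — condition, n_cells, mean_circularity,
#'   sd_circularity, mean_aspect_ratio, sd_aspect_ratio.
#'
#' @param particles per-particle data frame (see [extractParticles()]).
#' @param cells per-cell data frame (see [summarizeCells()]).
#' @param summaries per-condition data frame (see [summarizeCondition()]).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the three file paths.
#' @export
writeTables <- function(particles, cells, summaries, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopc("mitomorph_error_unwritable", "cannot create directory: %s", out_dir)
  if (nrow(particles) && nrow(cells)) {
    key <- function(d) paste(d$image, d$condition, d$cell_id)
    if (!all(key(particles) %in% key(cells)))
      stopc("mitomorph_error_inconsistent",
            "particle rows reference cell ids absent from the cell table")
  }
  paths <- c(particles = file.path(out_dir, "particles.csv"),
             cells = file.path(out_dir, "cells.csv"),
             conditions = file.path(out_dir, "conditions.csv"))
  write.csv(fmtNum(padCols(particles, particleCols)), paths["particles"],
            row.names = FALSE)
  write.csv(fmtNum(padCols(cells, cellCols)), paths["cells"],
            row.names = FALSE)
  write.csv(fmtNum(padCols(summaries, conditionCols)), paths["conditions"],
            row.names = FALSE)
  paths
}
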