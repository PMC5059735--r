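#' MultiChannelImage: registered single-plane channels bound to semantic roles
#'
#' Container for one field of view of a multi-channel 2-D fluorescence
#' acquisition. Planes are stored as numeric matrices (row, col) keyed by
#' channel role: \code{"nucleus"} (DNA stain), \code{"membrane"} (plasma
#' membrane stain) and \code{"mito"} (mitochondrial stain). All planes must
#' share the same dimensions and contain finite, non-negative intensities.
#' Automatic segmentation needs all three roles; semi-manual analysis (a
#' user-supplied cell mask) needs only \code{"mito"}.
#'
#' @slot planes named list of numeric matrices, one per channel role.
#' @slot pixelSize physical pixel edge length in micrometers.
#' @slot sourcePath provenance string (file the image was read from, or
#'   \code{"<synthetic>"}).
#'
#' @seealso [loadStack()], [renderScene()], [getPlane()]
#' @export
setClass("MultiChannelImage",
  representation(
    planes = "list",
    pixelSize = "numeric",
    sourcePath = "character"
  ),
  prototype(planes = list(), pixelSize = 0.2, sourcePath = "<memory>")
)

validMultiChannelImage <- function(object) {
  errs <- character()
  roles <- names(object@planes)
  allowed <- c("nucleus", "membrane", "mito")
  if (length(object@planes) == 0L) errs <- c(errs, "no channel planes")
  if (is.null(roles) || any(!nzchar(roles)))
    errs <- c(errs, "planes must be named by channel role")
  if (any(!roles %in% allowed))
    errs <- c(errs, sprintf("unknown channel role(s): %s",
                            paste(setdiff(roles, allowed), collapse = ", ")))
  if (anyDuplicated(roles)) errs <- c(errs, "duplicate channel roles")
  dims <- lapply(object@planes, dim)
  if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    errs <- c(errs, "all planes must share identical height x width")
  for (r in roles) {
    p <- object@planes[[r]]
    if (!is.matrix(p) || !is.numeric(p))
      errs <- c(errs, sprintf("plane '%s' is not a numeric matrix", r))
    else if (any(!is.finite(p)) || any(p < 0))
      errs <- c(errs, sprintf("plane '%s' has non-finite or negative values", r))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    errs <- c(errs, "pixelSize must be a single positive number")
  if (length(errs)) errs else TRUE
}
setValidity("MultiChannelImage", validMultiChannelImage)

#' LabelImage: integer-labeled segmentation map
#'
#' A 2-D map of non-negative integer labels where 0 is background. Labels are
#' object ids; they need not be contiguous (filtering keeps original ids).
#' The \code{kind} records what the objects are: \code{"nuclei"},
#' \code{"cells"} or \code{"particles"}.
#'
#' @slot labels integer matrix, 0 = background.
#' @slot kind one of \code{"nuclei"}, \code{"cells"}, \code{"particles"}.
#'
#' @seealso [segmentNuclei()], [segmentCells()], [loadLabelMask()]
#' @export
setClass("LabelImage",
  representation(labels = "matrix", kind = "character"),
  prototype(labels = matrix(0L, 0, 0), kind = "cells")
)

validLabelImage <- function(object) {
  errs <- character()
  if (!object@kind %in% c("nuclei", "cells", "particles"))
    errs <- c(errs, "kind must be one of 'nuclei', 'cells', 'particles'")
  l <- object@labels
  if (!is.numeric(l)) errs <- c(errs, "labels must be numeric")
  else {
    if (!isWholeNumber(l)) errs <- c(errs, "labels must be whole numbers")
    else if (any(l < 0)) errs <- c(errs, "labels must be >= 0")
  }
  if (length(errs)) errs else TRUE
}
setValidity("LabelImage", validLabelImage)

#' SyntheticScene: ground-truth geometry for a simulated field
#'
#' Vector-form ground truth for one simulated field of cells: star-convex
#' cell outlines (centre + radial Fourier perturbation), nucleus ellipses,
#' and per-cell mitochondrial skeletons (lists of polylines in pixel
#' coordinates, with a common tubule width). The fragmentation parameter
#' \code{f} used to generate the scene and the geometry seed are retained so
#' scenes are exactly reproducible and can be re-imaged under different
#' optics.
#'
#' @slot cells list, one element per cell: \code{center} (row, col),
#'   \code{radiusPx}, \code{pertAmp}, \code{pertPhase} (radial perturbation
#'   harmonics), \code{border} (logical, touches the image border).
#' @slot nuclei list, one per cell: \code{center}, \code{semiAxesPx} (a, b),
#'   \code{theta} orientation.
#' @slot fragments list, one per cell, each a list of fragments; a fragment
#'   is a list of polylines (n x 2 matrices of (row, col) pixel coordinates).
#' @slot tubuleWidthPx rendered tubule width (diameter) in pixels.
#' @slot f fragmentation parameter in [0, 1] used for generation.
#' @slot seed geometry seed used.
#' @slot imageSize integer (height, width) in pixels.
#' @slot pixelSize micrometers per pixel.
#'
#' @seealso [makeScene()], [renderScene()], [groundTruthMorphology()]
#' @export
setClass("SyntheticScene",
  representation(
    cells = "list",
    nuclei = "list",
    fragments = "list",
    tubuleWidthPx = "numeric",
    f = "numeric",
    seed = "numeric",
    imageSize = "integer",
    pixelSize = "numeric"
  )
)

validSyntheticScene <- function(object) {
  errs <- character()
  if (length(object@cells) != length(object@nuclei) ||
      length(object@cells) != length(object@fragments))
    errs <- c(errs, "cells, nuclei and fragments must have equal length")
  if (object@f < 0 || object@f > 1) errs <- c(errs, "f must lie in [0, 1]")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    errs <- c(errs, "imageSize must be two positive integers")
  if (object@tubuleWidthPx <= 0) errs <- c(errs, "tubuleWidthPx must be > 0")
  if (length(errs)) errs else TRUE
}
setValidity("SyntheticScene", validSyntheticScene)
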