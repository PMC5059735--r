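#' Accessors for image and label containers
#'
#' \code{getPlane} extracts one channel plane by role; \code{channelRoles}
#' lists the roles present; \code{pixelSize} returns micrometers per pixel;
#' \code{labelMatrix} and \code{labelKind} access a [LabelImage];
#' \code{objectIds} returns the sorted nonzero labels present;
#' \code{nObjects} their count; \code{nCells} the number of cells in a
#' [SyntheticScene].
#'
#' @param x a \linkS4class{MultiChannelImage}, \linkS4class{LabelImage} or
#'   \linkS4class{SyntheticScene}.
#' @param role channel role, one of \code{"nucleus"}, \code{"membrane"},
#'   \code{"mito"}.
#' @return \code{getPlane}: numeric matrix; \code{channelRoles}: character
#'   vector; \code{pixelSize}: numeric scalar; \code{labelMatrix}: integer
#'   matrix; \code{labelKind}: character; \code{objectIds}: integer vector;
#'   \code{nObjects}, \code{nCells}: integer scalars.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("getPlane", function(x, role) standardGeneric("getPlane"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("labelKind", function(x) standardGeneric("labelKind"))

#' @rdname accessors
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
setMethod("getPlane", "MultiChannelImage", function(x, role) {
  role <- match.arg(role, c("nucleus", "membrane", "mito"))
  if (!role %in% names(x@planes))
    stopc("mitomorph_error_missing_channel", "channel role '%s' not present", role)
  x@planes[[role]]
})

#' @rdname accessors
setMethod("channelRoles", "MultiChannelImage", function(x) names(x@planes))

#' @rdname accessors
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "SyntheticScene", function(x) x@pixelSize)

#' @rdname accessors
setMethod("labelMatrix", "LabelImage", function(x) x@labels)

#' @rdname accessors
setMethod("labelKind", "LabelImage", function(x) x@kind)

#' @rdname accessors
setMethod("objectIds", "LabelImage", function(x) {
  ids <- sort(unique(as.integer(x@labels)))
  ids[ids > 0L]
})

#' @rdname accessors
setMethod("nObjects", "LabelImage", function(x) length(objectIds(x)))

#' @rdname accessors
setMethod("nCells", "SyntheticScene", function(x) length(x@cells))

setMethod("show", "MultiChannelImage", function(object) {
  d <- if (length(object@planes)) dim(object@planes[[1]]) else c(0L, 0L)
  cat(sprintf("MultiChannelImage: %d x %d px, %.3g um/px\n", d[1], d[2],
              object@pixelSize))
  cat("  channels:", paste(names(object@planes), collapse = ", "), "\n")
  cat("  source:  ", object@sourcePath, "\n")
})

setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage (%s): %d x %d px, %d objects\n", object@kind,
              nrow(object@labels), ncol(object@labels), nObjects(object)))
})

setMethod("show", "SyntheticScene", function(object) {
  nfrag <- sum(vapply(object@fragments, length, integer(1)))
  cat(sprintf(
    "SyntheticScene: %d cells, %d mitochondrial fragments, f = %.2f\n",
    nCells(object), nfrag, object@f))
  cat(sprintf("  %d x %d px at %.3g um/px, geometry seed %d\n",
              object@imageSize[1], object@imageSize[2], object@pixelSize,
              as.integer(object@seed)))
})

#' Construct a MultiChannelImage
#'
#' @param planes named list of numeric matrices; names are channel roles
#'   among \code{nucleus}, \code{membrane}, \code{mito}.
#' @param pixelSize micrometers per pixel (default 0.2).
#' @param sourcePath provenance string.
#' @return A validated \linkS4class{MultiChannelImage}.
#' @export
#' @examples
#' MultiChannelImage(list(mito = matrix(0, 4, 4)))
MultiChannelImage <- function(planes, pixelSize = 0.2,
                              sourcePath = "<memory>") {
  new("MultiChannelImage", planes = planes, pixelSize = pixelSize,
      sourcePath = sourcePath)
}

#' Construct a LabelImage
#'
#' @param labels matrix of non-negative whole numbers (0 = background).
#' @param kind what the labels delineate: \code{"cells"}, \code{"nuclei"}
#'   or \code{"particles"}.
#' @return A validated \linkS4class{LabelImage}.
#' @export
#' @examples
#' LabelImage(matrix(c(0L, 1L, 1L, 2L), 2, 2))
LabelImage <- function(labels, kind = c("cells", "nuclei", "particles")) {
  kind <- match.arg(kind)
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, kind = kind)
}
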