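## segmentation: from (nucleus, membrane) channels to one mask per cell.
##
## The reference analysis created a per-cell mask from the nucleus and
## plasma-membrane stains; its original implementation is unpublished, so
## the reconstruction here uses the standard parameter-light chain:
## nuclei:  Gaussian smooth -> Otsu -> fill holes -> area filter ->
##          distance-transform watershed (h-maxima splitting of touching
##          nuclei);
## cells:   seeded region growing (Voronoi-like propagation) on the smoothed
##          membrane plane as elevation, seeded by the nuclei and restricted
##          to a cytoplasmic support = Otsu foreground of the smoothed
##          membrane + mito composite.

#' Segment nuclei from the nucleus channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling and an area
#' filter, followed by a distance-transform watershed whose h-maxima depth
#' (\code{split_h_maxima_depth}) splits touching nuclei. A blank (constant)
#' plane yields zero nuclei.
#'
#' @param img a \linkS4class{MultiChannelImage} with a \code{nucleus} plane.
#' @param params a [segmentationParams()] list.
#' @return A \linkS4class{LabelImage} of kind \code{"nuclei"}.
#' @export
#' @examples
#' sc <- makeScene(sceneParams(n_cells = 2, cell_radius_um = c(8, 10),
#'   image_size_px = 256, seed = 1))
#' img <- renderScene(sc, opticsParams(psf_sigma_px = 0, photon_scale = 0,
#'   gaussian_read_sd = 0, background_offset = 0, seed = 1))
#' nObjects(segmentNuclei(img, segmentationParams()))
segmentNuclei <- function(img, params = segmentationParams()) {
  if (!"nucleus" %in% channelRoles(img))
    stopc("mitomorph_error_missing_channel",
          "automatic segmentation requires a nucleus plane")
  plane <- getPlane(img, "nucleus")
  sm <- smoothPlane(plane, params$nucleus_smooth_sigma_px)
  thr <- otsuThreshold(as.vector(sm))
  if (is.na(thr))
    return(LabelImage(matrix(0L, nrow(plane), ncol(plane)), kind = "nuclei"))
  bin <- sm > thr
  bin <- as.matrix(EBImage::fillHull(bin)) > 0
  ## drop sub-threshold specks before the (costly) watershed
  lab0 <- labelConnected(bin, 8L)
  areas <- labelAreas(lab0)
  small <- as.integer(names(areas)[areas < params$nucleus_min_area_px])
  if (length(small)) bin[lab0 %in% small] <- FALSE
  if (!any(bin))
    return(LabelImage(matrix(0L, nrow(plane), ncol(plane)), kind = "nuclei"))
  dm <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dm, tolerance = params$split_h_maxima_depth, ext = 1)
  lab <- matrix(as.integer(ws), nrow(plane), ncol(plane))
  areas <- labelAreas(lab)
  small <- as.integer(names(areas)[areas < params$nucleus_min_area_px])
  if (length(small)) lab[lab %in% small] <- 0L
  LabelImage(relabelRaster(lab), kind = "nuclei")
}

#' Segment cells by nucleus-seeded growth on the membrane channel
#'
#' Regions grow from the nucleus seeds over the smoothed membrane plane
#' (bright membrane ridges act as basin boundaries), restricted to a
#' cytoplasmic support obtained by Otsu thresholding the smoothed sum of
#' the membrane and mito planes. Each retained nucleus yields exactly one
#' cell region containing it; regions are pairwise disjoint.
#'
#' @param img a \linkS4class{MultiChannelImage} with \code{membrane} and
#'   \code{mito} planes.
#' @param nuclei nuclei \linkS4class{LabelImage} computed on the same image.
#' @param params a [segmentationParams()] list.
#' @return A \linkS4class{LabelImage} of kind \code{"cells"}; empty (with a
#'   warning) if there are no nuclei.
#' @export
segmentCells <- function(img, nuclei, params = segmentationParams()) {
  stopifnot(is(nuclei, "LabelImage"))
  mem <- getPlane(img, "membrane")
  mito <- getPlane(img, "mito")
  if (!all(dim(labelMatrix(nuclei)) == dim(mem)))
    stopc("mitomorph_error_shape_mismatch",
          "nuclei label image does not match the image dimensions")
  if (nObjects(nuclei) == 0L) {
    warnc("mitomorph_warning_no_nuclei",
          "no nuclei seeds; returning empty cell map")
    return(LabelImage(matrix(0L, nrow(mem), ncol(mem)), kind = "cells"))
  }
  elev <- smoothPlane(mem, params$support_smooth_sigma_px)
  comp <- smoothPlane(mem + mito, params$support_smooth_sigma_px)
  ## the composite histogram is trimodal (background, cytoplasm, membrane
  ## ridge); Otsu on the log intensity separates background from cytoplasm
  ## instead of cytoplasm from ridge
  lcomp <- log1p(comp)
  thr <- otsuThreshold(as.vector(lcomp))
  support <- if (is.na(thr)) matrix(TRUE, nrow(mem), ncol(mem))
             else lcomp > thr
  ## smoothing dilates the bright membrane band outward by about sigma;
  ## pull the support edge back to the ridge centre
  er <- params$support_smooth_sigma_px
  if (er > 0 && any(support) && !all(support))
    support <- as.matrix(EBImage::distmap(support)) > er
  seeds <- labelMatrix(nuclei)
  support <- support | seeds > 0L   # seeds always belong to their own cell
  prop <- EBImage::propagate(elev, seeds = seeds, mask = support,
                             lambda = 1e-4)
  LabelImage(matrix(as.integer(prop), nrow(mem), ncol(mem)), kind = "cells")
}

#' Filter cells by area and border contact
#'
#' Removes cells smaller than \code{cell_min_area_px} and, when
#' \code{border_policy} is \code{"exclude"}, cells with any pixel on the
#' image border (truncated cells would bias the mitochondrial descriptors).
#' Surviving labels keep their original ids.
#'
#' @param cells a cells \linkS4class{LabelImage} (from [segmentCells()] or
#'   [loadLabelMask()]).
#' @param params a [segmentationParams()] list.
#' @param image_shape (height, width); defaults to the label image's own.
#' @return The filtered \linkS4class{LabelImage}.
#' @export
filterCells <- function(cells, params = segmentationParams(),
                        image_shape = dim(labelMatrix(cells))) {
  stopifnot(is(cells, "LabelImage"))
  lab <- labelMatrix(cells)
  drop <- integer(0)
  areas <- labelAreas(lab)
  drop <- c(drop, as.integer(names(areas)[areas < params$cell_min_area_px]))
  if (params$border_policy == "exclude") {
    border <- unique(c(lab[1, ], lab[image_shape[1], ],
                       lab[, 1], lab[, image_shape[2]]))
    drop <- unique(c(drop, border[border > 0L]))
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  LabelImage(lab, kind = "cells")
}
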