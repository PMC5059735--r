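## morphology: per-cell binarization of the mitochondrial channel, particle
## analysis, and the two shape descriptors (circularity, aspect ratio).
##
## Descriptor conventions follow the ImageJ particle-analysis tradition the
## reference read-out was built on:
##  - circularity = 4*pi*area/perimeter^2, clamped at 1, with the perimeter
##    estimated by the 4-direction Crofton formula (boundary-pixel counting
##    overestimates P and systematically depresses circularity);
##  - aspect ratio = major/minor axis of the moment-equivalent ellipse, each
##    pixel modelled as a unit square (adds 1/12 to each axis variance), so
##    single pixels and 1-px lines have finite, well-defined axes.

#' Binarize the mitochondrial channel per cell
#'
#' White top-hat background subtraction (square structuring element of
#' radius \code{tophat_radius_px}) followed by an Otsu threshold computed
#' separately over each cell's own pixels, so cells of different staining
#' brightness are binarized on equal footing. Pixels outside all cells are
#' background. A cell with (near-)constant intensity has no threshold and
#' contributes an empty mask, with a warning.
#'
#' @param mito_plane numeric matrix (mitochondrial channel), or a
#'   \linkS4class{MultiChannelImage} whose \code{mito} plane is used.
#' @param cell_mask cells \linkS4class{LabelImage}.
#' @param params a [morphologyParams()] list.
#' @return Logical matrix: foreground mitochondrial pixels.
#' @export
binarizeMito <- function(mito_plane, cell_mask,
                         params = morphologyParams()) {
  if (is(mito_plane, "MultiChannelImage"))
    mito_plane <- getPlane(mito_plane, "mito")
  stopifnot(is(cell_mask, "LabelImage"))
  lab <- labelMatrix(cell_mask)
  if (!all(dim(lab) == dim(mito_plane)))
    stopc("mitomorph_error_shape_mismatch",
          "cell mask does not match the mito plane dimensions")
  if (nObjects(cell_mask) == 0L)
    stopc("mitomorph_error_empty_mask", "cell mask contains no cells")
  th <- grayTopHat(mito_plane, params$tophat_radius_px)
  out <- matrix(FALSE, nrow(mito_plane), ncol(mito_plane))
  for (id in objectIds(cell_mask)) {
    idx <- which(lab == id)
    thr <- otsuThreshold(th[idx])
    if (is.na(thr)) {
      warnc("mitomorph_warning_constant_cell",
            "cell %d has constant intensity; empty mitochondrial mask", id)
      next
    }
    out[idx] <- th[idx] > thr
  }
  out
}

#' Moment-equivalent ellipse of a pixel set
#'
#' Central second moments of the pixel coordinates with each pixel modelled
#' as a unit square (adding 1/12 to both axis variances); the equivalent
#' ellipse axes are \code{4 * sqrt(eigenvalues)} of the covariance matrix.
#' For an axis-aligned solid w x h rectangle this gives an aspect ratio of
#' exactly \code{max(w, h) / min(w, h)}.
#'
#' @param coords n x 2 matrix of (row, col) pixel coordinates (any origin;
#'   the result is translation invariant).
#' @return List with \code{major_axis}, \code{minor_axis} (pixel units) and
#'   \code{aspect_ratio}.
#' @export
#' @examples
#' momentEllipse(cbind(rep(1:2, each = 6), rep(1:6, 2)))$aspect_ratio  # 3
momentEllipse <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L)
    stopc("mitomorph_error_empty_particle", "empty pixel set")
  n <- nrow(coords)
  mu <- colMeans(coords)
  dr <- coords[, 1] - mu[1]
  dc <- coords[, 2] - mu[2]
  srr <- sum(dr * dr) / n + 1 / 12
  scc <- sum(dc * dc) / n + 1 / 12
  src <- sum(dr * dc) / n
  tr <- srr + scc
  det <- srr * scc - src * src
  disc <- sqrt(max(0, tr * tr / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  list(major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
       aspect_ratio = sqrt(l1 / l2))
}

#' Aspect ratio of a pixel set
#'
#' Ratio of the major to the minor axis of the moment-equivalent ellipse
#' (see [momentEllipse()]); 1 for isotropic sets, large for tubules.
#'
#' @inheritParams momentEllipse
#' @return Numeric scalar \eqn{\ge} 1.
#' @export
aspectRatio <- function(coords) momentEllipse(coords)$aspect_ratio

## Crofton coefficients for 4 directions (0, 45, 90, 135 degrees), indexed
## by the 16 possible binary 2x2 pixel configurations.
croftonCoefs4 <- local({
  a <- pi / 4 * (1 + 1 / sqrt(2))
  b <- pi / (4 * sqrt(2))
  c(0, a, b, 2 * b, 0, a, 0, b, pi / 4, pi / 2, b, b, pi / 4, pi / 2, 0, 0)
})

#' Crofton perimeter of a binary mask
#'
#' Boundary-length estimate from intercept counts along 4 directions
#' (0, 45, 90, 135 degrees), computed from the histogram of 2 x 2 pixel
#' configurations. Less biased than counting boundary pixels; matches the
#' standard Crofton estimator used in image-analysis toolkits.
#'
#' @param mask logical (or 0/1) matrix; \code{TRUE} is foreground.
#' @return Perimeter estimate in pixel units.
#' @export
#' @examples
#' croftonPerimeter(matrix(TRUE, 10, 10))
croftonPerimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  n <- nrow(m); p <- ncol(m)
  tl <- m[-n, -p]; tr <- m[-n, -1]
  bl <- m[-1, -p]; br <- m[-1, -1]
  code <- 8L * tl + 2L * tr + 4L * bl + 1L * br
  h <- tabulate(code + 1L, nbins = 16L)
  sum(croftonCoefs4 * h)
}

#' Circularity from area and perimeter
#'
#' \code{4 * pi * area / perimeter^2}, clamped to at most 1 (the Crofton
#' estimator slightly underestimates the perimeter of very small objects,
#' which would otherwise push the value above the circular limit). Equals 1
#' for a continuous circle and \code{pi/4} for a continuous square.
#'
#' @param area_px particle area (pixels), > 0.
#' @param perimeter_px perimeter estimate (pixel units), > 0.
#' @return Circularity in (0, 1]. Vectorized.
#' @export
#' @examples
#' circularity(pi * 5^2, 2 * pi * 5)  # 1
#' circularity(4, 8)                  # square: pi/4
circularity <- function(area_px, perimeter_px) {
  if (any(area_px <= 0))
    stopc("mitomorph_error_bad_descriptor_input", "area must be > 0")
  if (any(perimeter_px <= 0))
    stopc("mitomorph_error_bad_descriptor_input", "perimeter must be > 0")
  pmin(1, 4 * pi * area_px / perimeter_px^2)
}

#' Particle analysis of a binarized mitochondrial mask
#'
#' Labels connected components (4- or 8-connectivity), drops components
#' below \code{min_particle_area_px}, assigns each particle to the cell
#' holding the majority of its pixels (components straddling a cell
#' boundary are not split), and computes area, Crofton perimeter,
#' moment-equivalent ellipse axes, aspect ratio, circularity and the
#' centroid (0-based (row, col), pixel centres).
#'
#' @param binary_mask logical matrix from [binarizeMito()].
#' @param cells cells \linkS4class{LabelImage}.
#' @param params a [morphologyParams()] list.
#' @return \code{data.frame} with one row per particle: \code{cell_id},
#'   \code{particle_id}, \code{area_px}, \code{perimeter_px},
#'   \code{major_axis_px}, \code{minor_axis_px}, \code{aspect_ratio},
#'   \code{circularity}, \code{centroid_row}, \code{centroid_col}.
#' @export
extractParticles <- function(binary_mask, cells,
                             params = morphologyParams()) {
  stopifnot(is(cells, "LabelImage"))
  lab <- labelMatrix(cells)
  mask <- (binary_mask > 0) & (lab > 0L)
  plab <- labelConnected(mask, params$connectivity)
  ids <- seq_len(max(plab))
  rows <- vector("list", length(ids))
  keep <- 0L
  nr <- nrow(mask)
  for (id in ids) {
    idx <- which(plab == id)
    if (length(idx) < params$min_particle_area_px) next
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    owners <- lab[idx]
    tab <- tabulate(owners)
    cell <- which.max(tab)   # majority vote; ties -> smallest label
    area <- length(idx)
    bb <- particleMask(r, c)
    per <- croftonPerimeter(bb)
    ell <- momentEllipse(cbind(r, c))
    keep <- keep + 1L
    rows[[keep]] <- data.frame(
      cell_id = as.integer(cell), particle_id = keep,
      area_px = area, perimeter_px = per,
      major_axis_px = ell$major_axis, minor_axis_px = ell$minor_axis,
      aspect_ratio = ell$aspect_ratio,
      circularity = circularity(area, per),
      centroid_row = mean(r) - 1, centroid_col = mean(c) - 1)
  }
  if (keep == 0L)
    return(data.frame(cell_id = integer(0), particle_id = integer(0),
                      area_px = integer(0), perimeter_px = numeric(0),
                      major_axis_px = numeric(0), minor_axis_px = numeric(0),
                      aspect_ratio = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  do.call(rbind, rows[seq_len(keep)])
}

## Tight binary mask of a pixel list (local bounding box).
particleMask <- function(r, c) {
  r0 <- min(r); c0 <- min(c)
  m <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
  m[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  m
}

#' Per-cell summary of mitochondrial particles
#'
#' Unweighted means of circularity and aspect ratio over each cell's
#' particles, plus the particle count and total mitochondrial area. Cells
#' listed in \code{all_cell_ids} but owning no particle are omitted with a
#' warning (they cannot enter descriptor statistics).
#'
#' @param particles data frame from [extractParticles()].
#' @param all_cell_ids optional integer vector of segmented cell ids, used
#'   to report cells without particles.
#' @return \code{data.frame} with columns \code{cell_id},
#'   \code{n_particles}, \code{mean_circularity}, \code{mean_aspect_ratio},
#'   \code{total_mito_area_px}, one row per cell with \eqn{\ge} 1 particle.
#' @export
summarizeCells <- function(particles, all_cell_ids = NULL) {
  if (!is.null(all_cell_ids)) {
    missing <- setdiff(all_cell_ids, particles$cell_id)
    if (length(missing))
      warnc("mitomorph_warning_empty_cells",
            "cell(s) without mitochondrial particles omitted: %s",
            paste(missing, collapse = ", "))
  }
  if (nrow(particles) == 0L)
    return(data.frame(cell_id = integer(0), n_particles = integer(0),
                      mean_circularity = numeric(0),
                      mean_aspect_ratio = numeric(0),
                      total_mito_area_px = numeric(0)))
  sp <- split(particles, particles$cell_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    cell_id = d$cell_id[1],
    n_particles = nrow(d),
    mean_circularity = mean(d$circularity),
    mean_aspect_ratio = mean(d$aspect_ratio),
    total_mito_area_px = sum(d$area_px))))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}
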