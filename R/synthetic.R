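## synthetic: ground-truth scene generation and the imaging model.
##
## A scene is a field of non-overlapping star-convex cells (radius profile
## r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k))), each with an
## elliptical nucleus and a mitochondrial skeleton drawn as smoothed
## random-walk polylines confined to the cytoplasm. A single fragmentation
## parameter f in [0, 1] interpolates the network from hyperfused (f = 0: a
## couple of long, optionally branched tubules) to fragmented (f = 1: many
## short punctate fragments): the expected fragment count is
## round(2 + 38 f) while the total skeleton length per cell is held at the
## length budget, so fragments shorten as f grows. Fragment masks are kept
## spatially separated so ground-truth fragment counts are recoverable.

polylineLength <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                    poly[-nrow(poly), , drop = FALSE])^2)))
}

fragmentLength <- function(frag) sum(vapply(frag, polylineLength, numeric(1)))

## radius of the star-convex outline at polar angle theta (radians)
cellRadiusAt <- function(cell, theta) {
  r <- rep(cell$radiusPx, length(theta))
  for (k in seq_along(cell$pertAmp))
    r <- r + cell$radiusPx * cell$pertAmp[k] *
      cos((k + 1) * theta + cell$pertPhase[k])
  r
}

## Evaluate d - r(theta) for a pixel grid around the cell; negative inside.
## Returns list(rows, cols, inside, band) over the clipped bounding box.
cellGeometry <- function(cell, imageSize, bandHalf = 1) {
  maxR <- cell$radiusPx * (1 + sum(cell$pertAmp))
  r0 <- max(1L, floor(cell$center[1] - maxR - 2))
  r1 <- min(imageSize[1], ceiling(cell$center[1] + maxR + 2))
  c0 <- max(1L, floor(cell$center[2] - maxR - 2))
  c1 <- min(imageSize[2], ceiling(cell$center[2] + maxR + 2))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cell$center[1], length(rows), length(cols))
  dx <- matrix(cols - cell$center[2], length(rows), length(cols),
               byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  rtheta <- matrix(cellRadiusAt(cell, as.vector(theta)),
                   length(rows), length(cols))
  list(rows = rows, cols = cols, signed = d - rtheta,
       band = abs(d - rtheta) <= bandHalf)
}

insideNucleus <- function(nuc, y, x, grow = 0) {
  dy <- y - nuc$center[1]; dx <- x - nuc$center[2]
  ct <- cos(nuc$theta); st <- sin(nuc$theta)
  u <- dy * ct + dx * st
  v <- -dy * st + dx * ct
  (u / (nuc$semiAxesPx[1] + grow))^2 + (v / (nuc$semiAxesPx[2] + grow))^2 <= 1
}

## signed test: is continuous point (y, x) an allowed skeleton location?
allowedPoint <- function(y, x, cell, nuc, marginIn) {
  dy <- y - cell$center[1]; dx <- x - cell$center[2]
  d <- sqrt(dy^2 + dx^2)
  if (d > cellRadiusAt(cell, atan2(dx, dy)) - marginIn) return(FALSE)
  !insideNucleus(nuc, y, x, grow = marginIn)
}

## Smoothed random walk of target length inside the cytoplasm, avoiding
## pixels already claimed (occupancy lookup by rounded coordinate).
walkPolyline <- function(start, targetLen, cell, nuc, marginIn, occupied,
                         step = 2, turnSd = 0.3, heading = NULL) {
  blocked <- function(y, x) {
    ry <- round(y); rx <- round(x)
    if (ry < 1 || rx < 1 || ry > nrow(occupied) || rx > ncol(occupied))
      return(TRUE)
    occupied[ry, rx]
  }
  if (is.null(heading)) heading <- runif(1, 0, 2 * pi)
  pts <- matrix(start, 1, 2)
  len <- 0
  while (len < targetLen) {
    adv <- min(step, targetLen - len)
    ok <- FALSE
    for (defl in c(0, 0.4, -0.4, 0.8, -0.8, 1.3, -1.3, 1.9, -1.9, 2.6, -2.6)) {
      h <- heading + defl
      cand <- pts[nrow(pts), ] + adv * c(cos(h), sin(h))
      if (allowedPoint(cand[1], cand[2], cell, nuc, marginIn) &&
          !blocked(cand[1], cand[2])) {
        heading <- h + rnorm(1, 0, turnSd)
        pts <- rbind(pts, cand)
        len <- len + adv
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)   # walled in; caller retries
  }
  pts
}

## Pixels (linear indices into imageSize) within width/2 of any polyline.
rasterFragment <- function(polys, widthPx, imageSize) {
  half <- widthPx / 2
  all <- do.call(rbind, polys)
  r0 <- max(1L, floor(min(all[, 1]) - half - 1))
  r1 <- min(imageSize[1], ceiling(max(all[, 1]) + half + 1))
  c0 <- max(1L, floor(min(all[, 2]) - half - 1))
  c1 <- min(imageSize[2], ceiling(max(all[, 2]) + half + 1))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows, length(rows), length(cols))
  xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d2min <- matrix(Inf, length(rows), length(cols))
  for (poly in polys) {
    if (nrow(poly) == 1L) {
      d2 <- (yy - poly[1, 1])^2 + (xx - poly[1, 2])^2
      d2min <- pmin(d2min, d2)
      next
    }
    for (s in seq_len(nrow(poly) - 1L)) {
      p <- poly[s, ]; q <- poly[s + 1L, ]
      v <- q - p
      vv <- sum(v * v)
      t <- ((yy - p[1]) * v[1] + (xx - p[2]) * v[2]) / vv
      t <- clampRange(t, 0, 1)
      d2 <- (yy - (p[1] + t * v[1]))^2 + (xx - (p[2] + t * v[2]))^2
      d2min <- pmin(d2min, d2)
    }
  }
  hit <- which(d2min <= half^2)
  if (!length(hit)) return(integer(0))
  rr <- rows[((hit - 1L) %% length(rows)) + 1L]
  cc <- cols[((hit - 1L) %/% length(rows)) + 1L]
  (cc - 1L) * imageSize[1] + rr
}

placeCells <- function(p) {
  ## rejection sampling with whole-field restarts: a single greedy pass can
  ## wall itself in when the radius draw is unlucky
  for (restart in seq_len(25L)) {
    cells <- tryCatch(placeCellsOnce(p), error = function(e) e)
    if (!inherits(cells, "error")) return(cells)
  }
  stop(cells)
}

placeCellsOnce <- function(p) {
  nTotal <- p$n_cells + p$n_border_cells
  px <- p$pixel_size_um
  radii <- sort(runif(nTotal, p$cell_radius_um[1], p$cell_radius_um[2]) / px,
                decreasing = TRUE)
  isBorder <- rep(c(FALSE, TRUE), c(p$n_cells, p$n_border_cells))
  cells <- list()
  maxRs <- numeric(0)
  for (i in seq_len(nTotal)) {
    amp <- runif(3, 0, 0.05)
    phase <- runif(3, 0, 2 * pi)
    maxR <- radii[i] * (1 + sum(amp))
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (isBorder[i]) {
        edge <- sample.int(4L, 1L)
        off <- runif(1, -0.2 * radii[i], 0.6 * radii[i])
        ctr <- switch(edge,
          c(off, runif(1, 1, p$image_size_px[2])),
          c(p$image_size_px[1] - off, runif(1, 1, p$image_size_px[2])),
          c(runif(1, 1, p$image_size_px[1]), off),
          c(runif(1, 1, p$image_size_px[1]), p$image_size_px[2] - off))
      } else {
        if (2 * maxR + 5 >= min(p$image_size_px)) break  # cannot fit at all
        ctr <- c(runif(1, maxR + 3, p$image_size_px[1] - maxR - 2),
                 runif(1, maxR + 3, p$image_size_px[2] - maxR - 2))
      }
      ok <- TRUE
      for (j in seq_along(cells)) {
        if (sqrt(sum((ctr - cells[[j]]$center)^2)) <=
            maxR + maxRs[j] + 6) { ok <- FALSE; break }
      }
      if (ok) {
        cells[[i]] <- list(center = ctr, radiusPx = radii[i],
                           pertAmp = amp, pertPhase = phase,
                           border = isBorder[i])
        maxRs[i] <- maxR
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopc("mitomorph_error_placement",
            "cannot place %d non-overlapping cells of radius %.0f-%.0f um in a %dx%d field",
            nTotal, p$cell_radius_um[1], p$cell_radius_um[2],
            p$image_size_px[1], p$image_size_px[2])
  }
  cells
}

makeNucleus <- function(cell) {
  a <- cell$radiusPx * runif(1, 0.28, 0.40)
  b <- a * runif(1, 0.65, 0.90)
  off <- runif(1, 0, 0.15 * cell$radiusPx)
  ang <- runif(1, 0, 2 * pi)
  list(center = cell$center + off * c(cos(ang), sin(ang)),
       semiAxesPx = c(a, b), theta = runif(1, 0, pi))
}

makeCellFragments <- function(cell, nuc, p, imageSize) {
  px <- p$pixel_size_um
  budget <- p$skeleton_length_budget_um / px
  width <- p$tubule_width_um / px
  nFrag <- max(1L, round(2 + p$f * 38))
  marginIn <- width / 2 + 1
  clear <- width + 3   # centre-line clearance between fragments
  for (cellTry in seq_len(8L)) {
    lens <- rgamma(nFrag, shape = 6)
    lens <- pmax(lens / sum(lens) * budget, 0.5)
    lens <- lens / sum(lens) * budget
    occ <- matrix(FALSE, imageSize[1], imageSize[2])
    frags <- vector("list", nFrag)
    failed <- FALSE
    for (i in order(lens, decreasing = TRUE)) {
      got <- NULL
      for (ftry in seq_len(40L)) {
        st <- sampleStart(cell, nuc, marginIn, occ)
        if (is.null(st)) next
        branch <- p$branch_prob * (1 - p$f) > runif(1) && lens[i] > 15
        mainLen <- if (branch) 0.7 * lens[i] else lens[i]
        main <- walkPolyline(st, mainLen, cell, nuc, marginIn, occ)
        if (is.null(main)) next
        polys <- list(main)
        if (branch) {
          v <- main[sample.int(max(1L, nrow(main) - 1L), 1L), ]
          h0 <- atan2(main[nrow(main), 2] - main[1, 2],
                      main[nrow(main), 1] - main[1, 1])
          br <- walkPolyline(v, lens[i] - mainLen, cell, nuc, marginIn, occ,
                             heading = h0 + sample(c(-1, 1), 1) *
                               runif(1, pi / 3, 2 * pi / 3))
          if (is.null(br)) next
          polys <- list(main, br)
        }
        got <- polys
        break
      }
      if (is.null(got)) { failed <- TRUE; break }
      frags[[i]] <- got
      occ[rasterFragment(got, 2 * clear, imageSize)] <- TRUE
    }
    if (!failed) return(frags)
  }
  stopc("mitomorph_error_placement",
        "cannot lay out %d mitochondrial fragments in a cell of radius %.0f px",
        nFrag, cell$radiusPx)
}

sampleStart <- function(cell, nuc, marginIn, occ) {
  for (k in seq_len(60L)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (cell$radiusPx - marginIn)
    y <- cell$center[1] + rad * cos(ang)
    x <- cell$center[2] + rad * sin(ang)
    if (!allowedPoint(y, x, cell, nuc, marginIn)) next
    ry <- round(y); rx <- round(x)
    if (ry < 1 || rx < 1 || ry > nrow(occ) || rx > ncol(occ)) next
    if (occ[ry, rx]) next
    return(c(y, x))
  }
  NULL
}

#' Generate a ground-truth synthetic scene
#'
#' Places \code{n_cells} non-overlapping star-convex cells (by rejection
#' sampling; an error is raised if the field cannot hold them), draws an
#' elliptical nucleus in each, and lays out the mitochondrial skeleton as
#' smoothed random-walk polylines confined to the cytoplasm, mutually
#' separated so fragments remain resolvable. The fragment count follows
#' \code{round(2 + 38 f)} and the total skeleton length per cell equals the
#' length budget. Deterministic given \code{params$seed}.
#'
#' @param params a [sceneParams()] list.
#' @return A \linkS4class{SyntheticScene}.
#' @export
#' @examples
#' sc <- makeScene(sceneParams(n_cells = 3, cell_radius_um = c(8, 10),
#'   image_size_px = 350, f = 1, seed = 2))
#' nCells(sc)
makeScene <- function(params = sceneParams()) {
  p <- do.call(sceneParams, unclass(params))   # validate
  withSeed(p$seed, {
    cells <- placeCells(p)
    nuclei <- lapply(cells, makeNucleus)
    frags <- vector("list", length(cells))
    for (i in seq_along(cells))
      frags[[i]] <- makeCellFragments(cells[[i]], nuclei[[i]], p,
                                      p$image_size_px)
    new("SyntheticScene", cells = cells, nuclei = nuclei, fragments = frags,
        tubuleWidthPx = p$tubule_width_um / p$pixel_size_um,
        f = p$f, seed = as.numeric(p$seed), imageSize = p$image_size_px,
        pixelSize = p$pixel_size_um)
  })
}

#' Ground-truth cell label image of a scene
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return \linkS4class{LabelImage} of kind \code{"cells"}; cell i has
#'   label i.
#' @export
groundTruthCellLabels <- function(scene) {
  lab <- matrix(0L, scene@imageSize[1], scene@imageSize[2])
  for (i in seq_along(scene@cells)) {
    g <- cellGeometry(scene@cells[[i]], scene@imageSize)
    sel <- which(g$signed < 0, arr.ind = TRUE)
    lab[cbind(g$rows[sel[, 1]], g$cols[sel[, 2]])] <- i
  }
  LabelImage(lab, kind = "cells")
}

#' Ground-truth nucleus label image of a scene
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return \linkS4class{LabelImage} of kind \code{"nuclei"}.
#' @export
groundTruthNucleusLabels <- function(scene) {
  lab <- matrix(0L, scene@imageSize[1], scene@imageSize[2])
  for (i in seq_along(scene@nuclei)) {
    nuc <- scene@nuclei[[i]]
    ext <- max(nuc$semiAxesPx) + 1
    r0 <- max(1L, floor(nuc$center[1] - ext))
    r1 <- min(scene@imageSize[1], ceiling(nuc$center[1] + ext))
    c0 <- max(1L, floor(nuc$center[2] - ext))
    c1 <- min(scene@imageSize[2], ceiling(nuc$center[2] + ext))
    if (r1 < r0 || c1 < c0) next
    rows <- r0:r1; cols <- c0:c1
    yy <- matrix(rows, length(rows), length(cols))
    xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    inside <- insideNucleus(nuc, yy, xx)
    lab[cbind(yy[inside], xx[inside])] <- i
  }
  LabelImage(lab, kind = "nuclei")
}

#' Ground-truth fragment label image of a scene
#'
#' Each mitochondrial fragment gets its own label (sequential across
#' cells); fragments are disjoint by construction.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return \linkS4class{LabelImage} of kind \code{"particles"}.
#' @export
groundTruthFragmentLabels <- function(scene) {
  lab <- matrix(0L, scene@imageSize[1], scene@imageSize[2])
  nxt <- 0L
  for (i in seq_along(scene@fragments)) {
    for (frag in scene@fragments[[i]]) {
      nxt <- nxt + 1L
      lab[rasterFragment(frag, scene@tubuleWidthPx, scene@imageSize)] <- nxt
    }
  }
  LabelImage(lab, kind = "particles")
}

#' Render a scene through the imaging model
#'
#' Channel construction: nucleus = filled ellipses; membrane = a bright
#' 2-px band along each cell outline over dim (0.15 relative) cytoplasm;
#' mito = skeletons dilated to the tubule width. Each channel is blurred
#' with a Gaussian PSF, scaled to photon counts, Poisson-sampled, and given
#' Gaussian read noise plus a constant offset. Deterministic given the
#' optics seed (derived from the geometry seed when not set).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param optics an [opticsParams()] list.
#' @return A \linkS4class{MultiChannelImage} with integer count planes.
#' @export
renderScene <- function(scene, optics = opticsParams()) {
  o <- do.call(opticsParams, unclass(optics))
  h <- scene@imageSize[1]; w <- scene@imageSize[2]
  nuc <- matrix(0, h, w)
  gl <- groundTruthNucleusLabels(scene)
  nuc[labelMatrix(gl) > 0L] <- 1
  mem <- matrix(0, h, w)
  for (cell in scene@cells) {
    g <- cellGeometry(cell, scene@imageSize, bandHalf = 1)
    inside <- which(g$signed < 0, arr.ind = TRUE)
    mem[cbind(g$rows[inside[, 1]], g$cols[inside[, 2]])] <-
      pmax(mem[cbind(g$rows[inside[, 1]], g$cols[inside[, 2]])], 0.15)
    band <- which(g$band, arr.ind = TRUE)
    mem[cbind(g$rows[band[, 1]], g$cols[band[, 2]])] <- 1
  }
  mito <- matrix(0, h, w)
  for (cf in scene@fragments)
    for (frag in cf)
      mito[rasterFragment(frag, scene@tubuleWidthPx, scene@imageSize)] <- 1
  seed <- if (is.null(o$seed)) as.integer(scene@seed) + 100000L else o$seed
  planes <- withSeed(seed, {
    lapply(list(nucleus = nuc, membrane = mem, mito = mito), function(pl) {
      b <- smoothPlane(pl, o$psf_sigma_px)
      counts <- rpois(length(b), pmax(0, b * o$photon_scale))
      counts <- counts + o$background_offset +
        rnorm(length(b), 0, o$gaussian_read_sd)
      matrix(round(clampRange(counts, 0, MAXCOUNT)), h, w)
    })
  })
  MultiChannelImage(planes, pixelSize = scene@pixelSize,
                    sourcePath = "<synthetic>")
}

#' Ground-truth morphology of a scene
#'
#' Runs the package's own descriptor operators (area, Crofton perimeter,
#' moment-equivalent ellipse) on the noiseless rasterized ground-truth
#' fragment masks, yielding the per-cell morphology the automatic pipeline
#' is expected to recover.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param params a [morphologyParams()] list (the particle-area floor is
#'   applied as in the pipeline).
#' @return List with \code{particles} and \code{cells} data frames (same
#'   schemas as [extractParticles()] / [summarizeCells()]).
#' @export
groundTruthMorphology <- function(scene, params = morphologyParams()) {
  rows <- list()
  pid <- 0L
  for (i in seq_along(scene@fragments)) {
    for (frag in scene@fragments[[i]]) {
      idx <- rasterFragment(frag, scene@tubuleWidthPx, scene@imageSize)
      if (length(idx) < params$min_particle_area_px) next
      r <- ((idx - 1L) %% scene@imageSize[1]) + 1L
      c <- ((idx - 1L) %/% scene@imageSize[1]) + 1L
      per <- croftonPerimeter(particleMask(r, c))
      ell <- momentEllipse(cbind(r, c))
      pid <- pid + 1L
      rows[[pid]] <- data.frame(
        cell_id = i, particle_id = pid, area_px = length(idx),
        perimeter_px = per, major_axis_px = ell$major_axis,
        minor_axis_px = ell$minor_axis, aspect_ratio = ell$aspect_ratio,
        circularity = circularity(length(idx), per),
        centroid_row = mean(r) - 1, centroid_col = mean(c) - 1)
    }
  }
  particles <- if (pid) do.call(rbind, rows) else
    extractParticles(matrix(FALSE, 1, 1), LabelImage(matrix(1L, 1, 1)))
  list(particles = particles, cells = summarizeCells(particles))
}

#' Write a simulated field and its ground truth to disk
#'
#' Renders the scene and writes \code{<base>_image.tif} (3-plane uint16:
#' nucleus, membrane, mito), \code{<base>_cells.tif},
#' \code{<base>_nuclei.tif}, \code{<base>_fragments.tif} (ground-truth
#' label masks) and \code{<base>_scene.json} (geometry, parameters, seeds).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param optics an [opticsParams()] list.
#' @param out_dir output directory (created if needed).
#' @param basename file name stem (default \code{"field"}).
#' @return Named character vector of the file paths.
#' @export
writeScene <- function(scene, optics = opticsParams(), out_dir,
                       basename = "field") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopc("mitomorph_error_unwritable", "cannot create directory: %s", out_dir)
  paths <- c(
    image = file.path(out_dir, paste0(basename, "_image.tif")),
    cells = file.path(out_dir, paste0(basename, "_cells.tif")),
    nuclei = file.path(out_dir, paste0(basename, "_nuclei.tif")),
    fragments = file.path(out_dir, paste0(basename, "_fragments.tif")),
    scene = file.path(out_dir, paste0(basename, "_scene.json")))
  writeStack(renderScene(scene, optics), paths["image"])
  writeLabelMask(groundTruthCellLabels(scene), paths["cells"])
  writeLabelMask(groundTruthNucleusLabels(scene), paths["nuclei"])
  writeLabelMask(groundTruthFragmentLabels(scene), paths["fragments"])
  sceneList <- list(
    f = scene@f, seed = scene@seed, image_size_px = scene@imageSize,
    pixel_size_um = scene@pixelSize, tubule_width_px = scene@tubuleWidthPx,
    optics = unclass(do.call(opticsParams, unclass(optics))),
    cells = scene@cells, nuclei = scene@nuclei,
    fragments = lapply(scene@fragments, function(cf)
      lapply(cf, function(frag) lapply(frag, unname))))
  jsonlite::write_json(sceneList, paths["scene"], auto_unbox = TRUE,
                       digits = 8, null = "null")
  paths
}
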