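## pipeline: orchestration of segmentation -> morphology -> statistics for
## single images, simulated conditions and batches of files.

#' Analyze one field: segmentation, binarization, particle analysis
#'
#' In \code{automatic} mode the cells are segmented from the nucleus and
#' membrane channels; in \code{semimanual} mode a user-supplied cell label
#' mask replaces segmentation and only the mito channel is required. Cell
#' filtering (area, border policy) applies in both modes.
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param config configuration list (see [defaultConfig()]).
#' @param mode \code{"automatic"} or \code{"semimanual"}.
#' @param cell_mask cells \linkS4class{LabelImage} or TIFF path (semimanual
#'   mode only).
#' @return List: \code{particles} and \code{cells} data frames,
#'   \code{cell_labels} and (automatic mode) \code{nucleus_labels}
#'   \linkS4class{LabelImage}s, and the binary mito mask \code{mito_mask}.
#' @export
analyzeImage <- function(img, config = defaultConfig(),
                         mode = c("automatic", "semimanual"),
                         cell_mask = NULL) {
  mode <- match.arg(mode)
  segP <- configSegParams(config)
  morphP <- configMorphParams(config)
  nuclei <- NULL
  if (mode == "automatic") {
    need <- c("nucleus", "membrane", "mito")
    miss <- setdiff(need, channelRoles(img))
    if (length(miss))
      stopc("mitomorph_error_missing_channel",
            "automatic mode requires channels: %s (missing %s)",
            paste(need, collapse = ", "), paste(miss, collapse = ", "))
    nuclei <- segmentNuclei(img, segP)
    cells <- segmentCells(img, nuclei, segP)
  } else {
    if (is.null(cell_mask))
      stopc("mitomorph_error_missing_mask",
            "semimanual mode requires a cell label mask")
    if (is.character(cell_mask)) cell_mask <- loadLabelMask(cell_mask)
    stopifnot(is(cell_mask, "LabelImage"))
    cells <- cell_mask
  }
  cells <- filterCells(cells, segP)
  empty <- list(
    particles = extractParticles(matrix(FALSE, 1, 1),
                                 LabelImage(matrix(1L, 1, 1))),
    cells = summarizeCells(data.frame(cell_id = integer(0),
                                      circularity = numeric(0),
                                      aspect_ratio = numeric(0),
                                      area_px = numeric(0))[0, ]),
    cell_labels = cells, nucleus_labels = nuclei, mito_mask = NULL)
  if (nObjects(cells) == 0L) {
    warnc("mitomorph_warning_no_cells", "no cells retained in this field")
    return(empty)
  }
  mask <- binarizeMito(getPlane(img, "mito"), cells, morphP)
  particles <- extractParticles(mask, cells, morphP)
  cellsDF <- withCallingHandlers(
    summarizeCells(particles, all_cell_ids = objectIds(cells)),
    mitomorph_warning_empty_cells = function(w) invokeRestart("muffleWarning"))
  list(particles = particles, cells = cellsDF, cell_labels = cells,
       nucleus_labels = nuclei, mito_mask = mask)
}

#' Simulate and analyze fields until a target cell count is reached
#'
#' Generates independent fields (geometry seed = \code{seed_start},
#' \code{seed_start + 1}, ...; optics seed derived per field), runs the
#' pipeline on each, and pools per-cell results until \code{n_cells} cells
#' are collected; the pool is truncated to exactly \code{n_cells}. This is
#' the in-silico analogue of quantifying a fixed number of cells per
#' experimental condition.
#'
#' @param f fragmentation parameter of the condition.
#' @param n_cells number of cells to collect (e.g. 30).
#' @param seed_start first geometry seed of the condition.
#' @param config configuration list; \code{config$synthetic} and
#'   \code{config$optics} define the generator and imaging model.
#' @param mode \code{"automatic"} (pipeline segmentation) or
#'   \code{"semimanual"} (ground-truth cell masks).
#' @param max_fields safety bound on the number of fields (default 40).
#' @return List: \code{cells} (with a \code{field_seed} column),
#'   \code{particles}, \code{ground_truth} (pooled [groundTruthMorphology()]
#'   cells over the same fields), \code{n_fields}.
#' @export
simulateConditionCells <- function(f, n_cells, seed_start,
                                   config = defaultConfig(),
                                   mode = c("automatic", "semimanual"),
                                   max_fields = 40L) {
  mode <- match.arg(mode)
  sp <- config$synthetic
  sp$f <- f
  cellsAcc <- list(); partAcc <- list(); gtAcc <- list()
  got <- 0L; fields <- 0L
  while (got < n_cells) {
    if (fields >= max_fields)
      stopc("mitomorph_error_no_cells",
            "collected only %d of %d cells after %d fields", got, n_cells,
            fields)
    fields <- fields + 1L
    sp$seed <- as.integer(seed_start) + fields - 1L
    scene <- makeScene(do.call(sceneParams, sp[setdiff(names(sp), "class")]))
    optics <- config$optics
    optics$seed <- sp$seed + 100000L
    img <- renderScene(scene, do.call(opticsParams, optics))
    res <- if (mode == "automatic")
      analyzeImage(img, config, mode = "automatic")
    else
      analyzeImage(img, config, mode = "semimanual",
                   cell_mask = groundTruthCellLabels(scene))
    if (nrow(res$cells) == 0L) next
    res$cells$field_seed <- sp$seed
    res$particles$field_seed <- sp$seed
    gt <- groundTruthMorphology(scene, configMorphParams(config))$cells
    gt$field_seed <- sp$seed
    cellsAcc[[fields]] <- res$cells
    partAcc[[fields]] <- res$particles
    gtAcc[[fields]] <- gt
    got <- got + nrow(res$cells)
  }
  cells <- do.call(rbind, cellsAcc)[seq_len(n_cells), , drop = FALSE]
  list(cells = cells, particles = do.call(rbind, partAcc),
       ground_truth = do.call(rbind, gtAcc), n_fields = fields)
}

#' Batch analysis of labelled images
#'
#' Processes a manifest of images (columns \code{image}, \code{condition},
#' optional \code{mask} for semimanual mode), pools particles and cells per
#' condition, writes the three CSV tables, a comparison table of every
#' condition against the first (the control), and a JSON run manifest
#' (configuration snapshot, package version, per-image counts, timestamps).
#'
#' @param manifest data frame, or path to a CSV with the same columns.
#' @param config configuration list (see [readConfig()]).
#' @param mode \code{"automatic"} or \code{"semimanual"}.
#' @param out_dir output directory.
#' @param save_masks if TRUE, write per-image nucleus/cell label TIFFs next
#'   to the tables (debug output).
#' @return Named vector of output paths, invisibly.
#' @export
analyzeBatch <- function(manifest, config = defaultConfig(),
                         mode = c("automatic", "semimanual"), out_dir,
                         save_masks = FALSE) {
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!all(c("image", "condition") %in% names(manifest)) ||
      nrow(manifest) == 0L)
    stopc("mitomorph_error_bad_manifest",
          "manifest needs at least one row with columns 'image', 'condition'")
  if (mode == "semimanual" && !"mask" %in% names(manifest))
    stopc("mitomorph_error_missing_mask",
          "semimanual mode requires a 'mask' column in the manifest")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partAcc <- list(); cellAcc <- list(); imgRows <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- loadStack(manifest$image[i], config$channel_map,
                     config$pixel_size_um)
    res <- analyzeImage(img, config, mode = mode,
                        cell_mask = if (mode == "semimanual")
                          manifest$mask[i] else NULL)
    base <- basename(manifest$image[i])
    message(sprintf("[mitomorph] %s (%s): %d cells, %d particles", base,
                    manifest$condition[i], nrow(res$cells),
                    nrow(res$particles)))
    if (nrow(res$cells)) {
      res$cells <- cbind(image = base, condition = manifest$condition[i],
                         res$cells)
      res$particles <- cbind(image = base, condition = manifest$condition[i],
                             res$particles)
      cellAcc[[i]] <- res$cells
      partAcc[[i]] <- res$particles
    }
    imgRows[[i]] <- data.frame(image = base,
                               condition = manifest$condition[i],
                               n_cells = nrow(res$cells),
                               n_particles = nrow(res$particles))
    if (save_masks && !is.null(res$cell_labels)) {
      writeLabelMask(res$cell_labels,
                     file.path(out_dir, paste0(tools::file_path_sans_ext(base),
                                               "_cells.tif")))
      if (!is.null(res$nucleus_labels))
        writeLabelMask(res$nucleus_labels,
                       file.path(out_dir,
                                 paste0(tools::file_path_sans_ext(base),
                                        "_nuclei.tif")))
    }
  }
  cells <- do.call(rbind, cellAcc)
  if (is.null(cells) || nrow(cells) == 0L)
    stopc("mitomorph_error_no_cells", "no cells found in any input image")
  particles <- do.call(rbind, partAcc)
  condLabels <- unique(manifest$condition)
  byCond <- lapply(condLabels, function(l) cells[cells$condition == l, ])
  names(byCond) <- condLabels
  byCond <- Filter(nrow, byCond)
  summaries <- do.call(rbind, lapply(names(byCond), function(l)
    summarizeCondition(byCond[[l]], l)))
  paths <- writeTables(particles, cells, summaries, out_dir)
  statsP <- configStatsParams(config)
  if (length(byCond) >= 2L) {
    cmp <- doseResponseTable(byCond, statsP)
    cmpPath <- file.path(out_dir, "comparisons.csv")
    write.csv(fmtNum(cmp), cmpPath, row.names = FALSE)
    paths <- c(paths, comparisons = cmpPath)
  }
  manifestPath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    tool = "mitomorph", version = as.character(utils::packageVersion("mitomorph")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = mode, config = config,
    images = do.call(rbind, imgRows)),
    manifestPath, auto_unbox = TRUE, digits = 8, null = "null")
  paths <- c(paths, manifest = manifestPath)
  invisible(paths)
}

#' Compare two per-cell CSV tables
#'
#' Welch (default) two-sided t-tests on the per-cell mean circularity and
#' mean aspect ratio of two cell tables written by [writeTables()] or
#' [analyzeBatch()].
#'
#' @param a,b per-cell data frames or CSV paths following the per-cell
#'   schema (must contain \code{mean_circularity}, \code{mean_aspect_ratio}).
#' @param labels group labels (default \code{c("A", "B")}).
#' @param params a [statsParams()] list.
#' @return Two-row comparison \code{data.frame} (see [compareGroups()]).
#' @export
compareCellTables <- function(a, b, labels = c("A", "B"),
                              params = statsParams()) {
  load1 <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x))
        stopc("mitomorph_error_missing_file", "file not found: %s", x)
      x <- read.csv(x)
    }
    need <- c("mean_circularity", "mean_aspect_ratio")
    if (!all(need %in% names(x)))
      stopc("mitomorph_error_schema",
            "cell table lacks required columns: %s",
            paste(setdiff(need, names(x)), collapse = ", "))
    x
  }
  a <- load1(a); b <- load1(b)
  rbind(
    compareGroups(a, b, "mean_circularity", labels, params),
    compareGroups(a, b, "mean_aspect_ratio", labels, params))
}
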