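test_that("blank nucleus plane yields zero nuclei", {
  img <- MultiChannelImage(list(nucleus = matrix(7, 64, 64)))
  expect_equal(nObjects(segmentNuclei(img)), 0L)
})

test_that("two overlapping nuclei are split by the distance watershed", {
  plane <- matrix(0, 120, 120)
  ## two discs of radius 20, centres 30 px apart (1.5 radii): one blob
  for (ctr in list(c(60, 45), c(60, 75)))
    plane[(row(plane) - ctr[1])^2 + (col(plane) - ctr[2])^2 <= 400] <- 100
  img <- MultiChannelImage(list(nucleus = plane))
  nuc <- segmentNuclei(img, segmentationParams(nucleus_smooth_sigma_px = 1))
  expect_equal(nObjects(nuc), 2L)
})

test_that("nuclei of a synthetic field are recovered near their centres", {
  sc <- smallScene(f = 0.5, seed = 11, n_cells = 3)
  img <- renderScene(sc)
  nuc <- segmentNuclei(img)
  expect_equal(nObjects(nuc), 3L)
  lab <- labelMatrix(nuc)
  for (i in seq_len(3)) {
    truth <- sc@nuclei[[i]]$center
    id <- lab[round(truth[1]), round(truth[2])]
    expect_gt(id, 0L)
    idx <- which(lab == id, arr.ind = TRUE)
    expect_lt(sqrt(sum((colMeans(idx) - truth)^2)), 3)
  }
})

test_that("cell segmentation recovers interior cells with high overlap", {
  sc <- makeScene(sceneParams(n_cells = 10, cell_radius_um = c(8, 11),
                              image_size_px = 640, f = 0.5, seed = 5))
  img <- renderScene(sc)
  cells <- filterCells(segmentCells(img, segmentNuclei(img)),
                       segmentationParams(cell_min_area_px = 1000))
  expect_equal(nObjects(cells), 10L)
  gtl <- labelMatrix(groundTruthCellLabels(sc))
  cl <- labelMatrix(cells)
  for (i in seq_len(10)) {
    ids <- cl[gtl == i]
    id <- as.integer(names(sort(table(ids[ids > 0]), decreasing = TRUE))[1])
    jac <- sum(gtl == i & cl == id) / sum(gtl == i | cl == id)
    expect_gte(jac, 0.9)
  }
})

test_that("cell regions are disjoint and contain exactly one seed nucleus", {
  sc <- smallScene(f = 0.25, seed = 8)
  img <- renderScene(sc)
  nuc <- segmentNuclei(img)
  cells <- segmentCells(img, nuc)
  cl <- labelMatrix(cells); nl <- labelMatrix(nuc)
  expect_setequal(objectIds(cells), objectIds(nuc))
  for (id in objectIds(cells)) {
    inside <- unique(nl[cl == id & nl > 0L])
    expect_identical(inside, id)      # its own seed, whole and alone
  }
})

test_that("degenerate elevations are handled", {
  ## one nucleus, uniform membrane: single cell covering the whole support
  seed <- matrix(0L, 80, 80)
  seed[(row(seed) - 40)^2 + (col(seed) - 40)^2 <= 100] <- 1L
  img <- MultiChannelImage(list(nucleus = matrix(0, 80, 80),
                                membrane = matrix(5, 80, 80),
                                mito = matrix(0, 80, 80)))
  cells <- segmentCells(img, LabelImage(seed, kind = "nuclei"))
  expect_equal(sum(labelMatrix(cells) == 1L), 80L * 80L)

  ## zero nuclei: empty map plus warning
  expect_warning(
    empty <- segmentCells(img, LabelImage(matrix(0L, 80, 80), "nuclei")),
    class = "mitomorph_warning_no_nuclei")
  expect_equal(nObjects(empty), 0L)
})

test_that("segmentation is deterministic", {
  sc <- smallScene(f = 1, seed = 13)
  img <- renderScene(sc)
  a <- segmentCells(img, segmentNuclei(img))
  b <- segmentCells(img, segmentNuclei(img))
  expect_identical(labelMatrix(a), labelMatrix(b))
})

test_that("cell filtering removes small and border cells, preserving labels", {
  m <- matrix(0L, 40, 40)
  m[1:12, 5:20] <- 1L      # touches row 1
  m[20:34, 3:30] <- 2L     # interior, large
  m[36:38, 36:38] <- 3L    # interior, tiny
  lab <- LabelImage(m, "cells")
  p <- segmentationParams(cell_min_area_px = 50)
  kept <- filterCells(lab, p)
  expect_identical(objectIds(kept), 2L)
  keptAll <- filterCells(lab, segmentationParams(cell_min_area_px = 50,
                                                 border_policy = "keep"))
  expect_setequal(objectIds(keptAll), c(1L, 2L))
})

test_that("border cells of a synthetic field are excluded, interior kept", {
  sc <- makeScene(sceneParams(n_cells = 3, n_border_cells = 2,
                              cell_radius_um = c(8, 11),
                              image_size_px = 420, f = 0.5, seed = 21))
  gtl <- groundTruthCellLabels(sc)
  kept <- filterCells(gtl, segmentationParams(cell_min_area_px = 1000))
  borderIds <- which(vapply(sc@cells, `[[`, logical(1), "border"))
  expect_setequal(objectIds(kept), setdiff(seq_len(5), borderIds))
})

test_that("recovered cell count matches ground truth across seeds", {
  hits <- 0L
  nFields <- 20L
  for (s in seq_len(nFields)) {
    sc <- smallScene(f = 0.5, seed = 400 + s)
    img <- renderScene(sc)
    cells <- filterCells(segmentCells(img, segmentNuclei(img)),
                         segmentationParams(cell_min_area_px = 1000))
    if (nObjects(cells) == 3L) hits <- hits + 1L
  }
  expect_gte(hits / nFields, 0.95)
})
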