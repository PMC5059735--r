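test_that("scene generation is deterministic and respects cell count", {
  p <- sceneParams(n_cells = 7, cell_radius_um = c(8, 11),
                   image_size_px = 560, f = 0.3, seed = 4)
  a <- makeScene(p)
  b <- makeScene(p)
  expect_equal(nCells(a), 7L)
  expect_identical(a@cells, b@cells)
  expect_identical(a@fragments, b@fragments)
})

test_that("fragment count and length budget follow the fragmentation model", {
  budgetPx <- 15 / 0.2
  for (f in c(0, 0.5, 1)) {
    sc <- smallScene(f = f, seed = 40 + round(10 * f))
    nfrag <- vapply(sc@fragments, length, integer(1))
    expect_true(all(nfrag == max(1, round(2 + 38 * f))))
    for (cf in sc@fragments) {
      total <- sum(vapply(cf, mitomorph:::fragmentLength, numeric(1)))
      expect_lt(abs(total - budgetPx) / budgetPx, 0.05)
    }
  }
})

test_that("fragments shorten as fragmentation increases", {
  fused <- smallScene(f = 0, seed = 51)
  frag <- smallScene(f = 1, seed = 52)
  meanLen <- function(sc)
    mean(unlist(lapply(sc@fragments, function(cf)
      vapply(cf, mitomorph:::fragmentLength, numeric(1)))))
  expect_lt(meanLen(frag), meanLen(fused))
})

test_that("skeletons stay inside their cell and outside the nucleus", {
  sc <- smallScene(f = 0.25, seed = 53)
  cellLab <- labelMatrix(groundTruthCellLabels(sc))
  nucLab <- labelMatrix(groundTruthNucleusLabels(sc))
  fragLab <- labelMatrix(groundTruthFragmentLabels(sc))
  ## cells pairwise disjoint is implied by a single-valued label map;
  ## check fragment pixels live in the right compartment
  for (i in seq_len(nCells(sc))) {
    ids <- unique(fragLab[cellLab == i])
    own <- setdiff(ids, 0L)
    expect_gt(length(own), 0L)
    pix <- fragLab %in% own
    expect_true(all(cellLab[pix] == i))
    expect_true(!any(nucLab[pix] > 0L))
  }
})

test_that("ground-truth descriptors span punctate to tubular regimes", {
  ## full-size cells as in the default study conditions
  punct <- makeScene(sceneParams(n_cells = 1, image_size_px = 420, f = 1,
                                 seed = 61))
  gtp <- groundTruthMorphology(punct)
  expect_gt(mean(gtp$cells$mean_circularity), 0.8)
  expect_equal(nrow(gtp$particles), length(punct@fragments[[1]]))

  fused <- makeScene(sceneParams(n_cells = 1, image_size_px = 420, f = 0,
                                 seed = 62))
  gtf <- groundTruthMorphology(fused)
  expect_gt(mean(gtf$cells$mean_aspect_ratio), 3)
  expect_gt(mean(gtp$cells$mean_circularity),
            mean(gtf$cells$mean_circularity))
})

test_that("the imaging model degenerates correctly and is deterministic", {
  sc <- smallScene(f = 0.5, seed = 71)
  ## no photons, no read noise: constant offset everywhere
  dark <- renderScene(sc, opticsParams(photon_scale = 0,
                                       gaussian_read_sd = 0,
                                       background_offset = 10, seed = 1))
  for (r in channelRoles(dark))
    expect_true(all(getPlane(dark, r) == 10))

  ## identity optics: mito support equals the dilated skeleton mask
  ideal <- renderScene(sc, cleanOptics(psf = 0, seed = 1))
  gt <- labelMatrix(groundTruthFragmentLabels(sc)) > 0L
  expect_identical(getPlane(ideal, "mito") > 0, gt)

  ## same scene + same optics seed: identical images
  o <- opticsParams(seed = 99)
  expect_identical(renderScene(sc, o)@planes, renderScene(sc, o)@planes)
})

test_that("scene files round-trip and are byte-stable across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sc <- smallScene(f = 0.5, seed = 81)
  o <- opticsParams(seed = 81)
  p1 <- writeScene(sc, o, d1)
  p2 <- writeScene(makeScene(sceneParams(n_cells = 3,
                                         cell_radius_um = c(8, 11),
                                         image_size_px = 360, f = 0.5,
                                         seed = 81)), o, d2)
  expect_true(all(file.exists(p1)))
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[k])),
                     unname(tools::md5sum(p2[k])))
  ## the written image reloads into the rendered counts
  img <- renderScene(sc, o)
  back <- loadStack(p1["image"], list(nucleus = 1, membrane = 2, mito = 3))
  expect_equal(getPlane(back, "mito"), getPlane(img, "mito"),
               ignore_attr = TRUE)
  ## label mask round-trip
  lab <- loadLabelMask(p1["cells"])
  expect_identical(labelMatrix(lab),
                   labelMatrix(groundTruthCellLabels(sc)))
})

test_that("impossible packing raises a placement error", {
  expect_error(
    makeScene(sceneParams(n_cells = 10, cell_radius_um = c(15, 25),
                          image_size_px = 256, seed = 1)),
    class = "mitomorph_error_placement")
})
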