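test_that("per-cell Otsu binarization recovers structures at any brightness", {
  ## two cells with identical structures, one 20x dimmer
  lab <- matrix(0L, 60, 120)
  lab[6:55, 6:55] <- 1L
  lab[6:55, 66:115] <- 2L
  plane <- matrix(0, 60, 120)
  plane[20:30, 20:30] <- 200   # bright cell's structure
  plane[20:30, 80:90] <- 10    # dim cell's structure
  plane <- plane + 1
  mask <- binarizeMito(plane, LabelImage(lab), morphologyParams())
  expect_true(all(mask[20:30, 20:30]))
  expect_true(all(mask[20:30, 80:90]))
  expect_false(any(mask[lab == 0L]))

  ## constant-intensity cell: empty mask with warning
  expect_warning(
    m <- binarizeMito(matrix(3, 20, 20), LabelImage(matrix(1L, 20, 20))),
    class = "mitomorph_warning_constant_cell")
  expect_false(any(m))
})

test_that("binarization is invariant to image-wide intensity rescaling", {
  sc <- smallScene(f = 0.75, seed = 31)
  img <- renderScene(sc)
  cells <- groundTruthCellLabels(sc)
  plane <- getPlane(img, "mito")
  m1 <- binarizeMito(plane, cells)
  m2 <- binarizeMito(plane * 3.7, cells)
  expect_identical(m1, m2)
})

test_that("binarized mask overlaps ground-truth mitochondria", {
  sc <- smallScene(f = 0.5, seed = 17)
  img <- renderScene(sc, cleanOptics(seed = 17))
  cells <- groundTruthCellLabels(sc)
  mask <- binarizeMito(getPlane(img, "mito"), cells)
  gt <- labelMatrix(groundTruthFragmentLabels(sc)) > 0L
  jac <- sum(mask & gt) / sum(mask | gt)
  expect_gte(jac, 0.8)
})

test_that("particle extraction obeys connectivity and area floor", {
  lab <- LabelImage(matrix(1L, 20, 20))
  mask <- matrix(FALSE, 20, 20)
  mask[3:7, 3:7] <- TRUE
  mask[12:16, 12:16] <- TRUE
  parts <- extractParticles(mask, lab)
  expect_equal(nrow(parts), 2L)
  expect_equal(parts$area_px, c(25L, 25L))
  expect_equal(parts$cell_id, c(1L, 1L))

  ## diagonal chain: one particle under 8-connectivity, n under 4
  lab10 <- LabelImage(matrix(1L, 10, 10))
  diagm <- matrix(FALSE, 10, 10)
  for (i in 2:7) diagm[i, i] <- TRUE
  p8 <- extractParticles(diagm, lab10,
                         morphologyParams(min_particle_area_px = 1))
  expect_equal(nrow(p8), 1L)
  p4 <- extractParticles(diagm, lab10,
                         morphologyParams(min_particle_area_px = 1,
                                          connectivity = 4))
  expect_equal(nrow(p4), 6L)

  ## sub-floor specks are dropped
  speck <- matrix(FALSE, 10, 10); speck[5, 5] <- TRUE
  expect_equal(nrow(extractParticles(speck, lab10)), 0L)
})

test_that("particles straddling two cells are assigned by majority vote", {
  lab <- matrix(0L, 20, 30)
  lab[, 1:14] <- 1L; lab[, 15:30] <- 2L
  mask <- matrix(FALSE, 20, 30)
  mask[10:12, 12:20] <- TRUE   # 9 columns: 3 in cell 1, 6 in cell 2
  parts <- extractParticles(mask, LabelImage(lab))
  expect_equal(nrow(parts), 1L)
  expect_equal(parts$cell_id, 2L)
})

test_that("noiseless fragmented field yields ground-truth particle count", {
  sc <- smallScene(f = 1, seed = 19)
  img <- renderScene(sc, cleanOptics(psf = 0, seed = 19))
  cells <- groundTruthCellLabels(sc)
  mask <- binarizeMito(getPlane(img, "mito"), cells)
  parts <- extractParticles(mask, cells)
  gt <- groundTruthMorphology(sc)
  expect_equal(nrow(parts), nrow(gt$particles))
})

test_that("moment-equivalent ellipse matches analytic shapes", {
  expect_equal(aspectRatio(matrix(c(5, 5), 1, 2)), 1)      # single pixel
  for (wh in list(c(3, 3), c(2, 6), c(1, 7), c(4, 10))) {
    coords <- as.matrix(expand.grid(seq_len(wh[1]), seq_len(wh[2])))
    expect_equal(aspectRatio(coords), max(wh) / min(wh), tolerance = 1e-12)
  }
  ## rasterized disc is isotropic
  ar <- aspectRatio(maskCoords(discMask(20)))
  expect_gte(ar, 1); expect_lte(ar, 1.05)
  expect_error(momentEllipse(matrix(0, 0, 2)),
               class = "mitomorph_error_empty_particle")
})

test_that("Crofton perimeter reproduces independent reference values", {
  ## frozen from an independent Crofton implementation (4 directions)
  expect_equal(croftonPerimeter(discMask(20)), 127.71373126734748)
  expect_equal(croftonPerimeter(matrix(TRUE, 10, 7)), 31.123300530390082)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(croftonPerimeter(single), 2.681517061334488)
  domino <- matrix(FALSE, 5, 5); domino[3, 3:4] <- TRUE
  expect_equal(croftonPerimeter(domino), 4.577635959271528)
})

test_that("circularity follows the analytic formula with clamping", {
  expect_equal(circularity(pi * 7^2, 2 * pi * 7), 1)
  expect_equal(circularity(9, 12), pi / 4)
  d <- discMask(20)
  circ <- circularity(sum(d), croftonPerimeter(d))
  expect_gte(circ, 0.9); expect_lte(circ, 1)
  expect_equal(circularity(100, 1), 1)   # clamped
  expect_error(circularity(0, 5),
               class = "mitomorph_error_bad_descriptor_input")
})

test_that("descriptors are exactly invariant to rotations, flips, shifts", {
  set.seed(42)
  for (rep in seq_len(10)) {
    m <- matrix(runif(15 * 12) > 0.55, 15, 12)
    if (!any(m)) next
    variants <- list(t(m), m[nrow(m):1, ], m[, ncol(m):1])
    per <- croftonPerimeter(m)
    ar <- aspectRatio(maskCoords(m))
    for (v in variants) {
      expect_equal(croftonPerimeter(v), per, tolerance = 1e-12)
      expect_equal(aspectRatio(maskCoords(v)), ar, tolerance = 1e-12)
    }
    shifted <- maskCoords(m); shifted[, 1] <- shifted[, 1] + 100
    expect_equal(aspectRatio(shifted), ar, tolerance = 1e-12)
  }
})

test_that("per-cell summaries are unweighted particle means", {
  one <- data.frame(cell_id = 1L, circularity = 0.37, aspect_ratio = 2.5,
                    area_px = 10)
  s <- summarizeCells(one)
  expect_equal(s$mean_circularity, 0.37)
  expect_equal(s$n_particles, 1L)

  two <- data.frame(cell_id = c(2L, 2L), circularity = c(0.4, 0.8),
                    aspect_ratio = c(1, 3), area_px = c(5, 15))
  s <- summarizeCells(two)
  expect_equal(s$mean_circularity, 0.6)
  expect_equal(s$mean_aspect_ratio, 2)
  expect_equal(s$total_mito_area_px, 20)

  set.seed(9)
  rand <- data.frame(cell_id = sample(1:5, 60, TRUE),
                     circularity = runif(60), aspect_ratio = 1 + runif(60),
                     area_px = sample(4:50, 60, TRUE))
  s <- summarizeCells(rand)
  for (id in s$cell_id) {
    sub <- rand[rand$cell_id == id, ]
    expect_equal(s$mean_circularity[s$cell_id == id], mean(sub$circularity))
    expect_equal(s$mean_aspect_ratio[s$cell_id == id],
                 mean(sub$aspect_ratio))
  }

  expect_warning(summarizeCells(two, all_cell_ids = c(2L, 3L)),
                 class = "mitomorph_warning_empty_cells")
})
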