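# mitomorph

Automated per-cell quantification of mitochondrial fragmentation in
multi-channel live-cell fluorescence microscopy.

Mitochondria continuously fuse and divide; stressors (UVB irradiation,
uncouplers) shift the balance toward fission, turning long tubular networks
into many small punctate organelles, while knocking down the fission GTPase
DRP1 drives hyperfusion. Because network shape is a sensitive readout of
cell state, quantifying it objectively — rather than by eye — is the basis
of screens for mitoprotective compounds. `mitomorph` implements the
standard confocal readout for this: each cell in a three-channel field
(nucleus stain, plasma-membrane stain, mitochondrial stain) is segmented,
its mitochondrial channel is binarized, and every mitochondrial particle is
summarised by two dimensionless shape descriptors:

- **circularity** `4·π·A / P²` — area `A` in pixels, perimeter `P` by the
  4-direction Crofton estimator, clamped at 1. Near 1 for fragmented
  puncta, small for elongated or branched tubules.
- **aspect ratio (AR)** — ratio of the major to minor axis of the ellipse
  with the same second central moments as the particle (each pixel treated
  as a unit square). 1 for isotropic shapes, large for tubules.

Fragmentation therefore reads out as circularity up, AR down. Per-cell
means are aggregated per condition (mean ± SD over cells) and compared with
two-sided Welch t-tests (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).

The pipeline has two modes, mirroring common practice:

- **automatic** — nuclei: Gaussian smoothing, Otsu, hole filling,
  distance-transform watershed; cells: nucleus-seeded growth on the
  smoothed membrane channel restricted to a cytoplasmic support; border
  and undersized cells are excluded.
- **semi-manual** — a user-supplied cell label mask (e.g. exported from
  manual delimitation in Fiji/ImageJ) replaces segmentation.

Binarization is per cell: white top-hat background subtraction followed by
an Otsu threshold computed over each cell's own pixels, so dim and bright
cells are treated on equal footing.

Because no public dataset accompanies this kind of assay, the package
ships a **synthetic-scene generator** with exact ground truth: fields of
star-convex cells with elliptical nuclei and mitochondrial skeletons drawn
as confined random walks. One parameter `f ∈ [0, 1]` interpolates from a
hyperfused network (two long, optionally branched tubules per cell) to full
fragmentation (~40 short puncta), holding total skeleton length fixed;
rendering applies a Gaussian PSF, Poisson shot noise, Gaussian read noise
and a camera offset. Every pipeline stage is validated against this ground
truth.

## Worked example

Simulate one strongly fragmented field, analyse it automatically, and look
at the per-cell summaries:

```r
library(mitomorph)

scene <- makeScene(sceneParams(f = 0.75, seed = 1))
scene
#> SyntheticScene: 10 cells, 300 mitochondrial fragments, f = 0.75
#>   1024 x 1024 px at 0.2 um/px, geometry seed 1

img <- renderScene(scene)          # nucleus / membrane / mito channels
res <- analyzeImage(img)           # segment -> binarize -> particles
head(res$cells)
#>   cell_id n_particles mean_circularity mean_aspect_ratio total_mito_area_px
#> 1       1          30        0.9408930          1.345320               1135
#> 2       2          30        0.9417910          1.341774               1120
#> 3       3          30        0.9485616          1.324836               1108
#> 4       4          30        0.9351374          1.315976               1107
#> 5       5          30        0.9420310          1.320635               1131
#> 6       6          30        0.9424380          1.303483               1098
```

All 30 ground-truth fragments per cell are recovered, and the punctate
regime shows the expected signature (circularity ≈ 0.94, AR ≈ 1.3). A
two-condition experiment with 30 cells per condition — a mildly fragmented
control (`f = 0.15`) versus a fragmented state (`f = 0.75`) — gives:

```r
ctrl <- simulateConditionCells(f = 0.15, n_cells = 30, seed_start = 1)
frag <- simulateConditionCells(f = 0.75, n_cells = 30, seed_start = 31)
compareCellTables(ctrl$cells, frag$cells, labels = c("control", "fragmented"))
#>          descriptor  group_a    group_b ... mean_a    mean_b          p stars
#> 1  mean_circularity  control fragmented ... 0.762     0.936   1.61e-53   ***
#> 2 mean_aspect_ratio  control fragmented ... 2.239     1.317   2.86e-33   ***
```

Circularity rises and aspect ratio falls, both far beyond the `***`
threshold — the dose-dependent fragmentation signature.

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "mitomorph.R", package = "mitomorph")`):

```sh
mitomorph.R simulate --f 0.75 --seed 1 --n-fields 3 --out fixtures/
mitomorph.R analyze  --manifest images.csv --config cfg.yaml --out results/
mitomorph.R compare  --a results_a/cells.csv --b results_b/cells.csv
```

`analyze` writes `particles.csv`, `cells.csv`, `conditions.csv`,
`comparisons.csv` (every condition against the first, the control) and a
JSON run manifest with the full configuration snapshot. The manifest CSV
maps each image to a condition (plus a `mask` column in semi-manual mode).

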