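---
title: "Quantifying mitochondrial fragmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial fragmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitomorph` quantifies the fission–fusion state of mitochondrial networks
from three-channel live-cell confocal fields, one number pair per particle:
circularity and aspect ratio. This vignette documents the model behind each
stage, the tunable parameters and their defaults, the synthetic validation
design, and the choices made where the design was genuinely open.

## The measurement model

The unit of analysis is the **cell**. For each segmented cell we binarize
the mitochondrial channel, label connected components ("particles"), and
compute per particle:

- area $A$ (pixel count);
- perimeter $P$ by the 4-direction Crofton estimator: the histogram of the
  sixteen $2\times2$ binary pixel configurations is contracted with fixed
  weights corresponding to intercept counts along 0°, 45°, 90° and 135°.
  Naive boundary-pixel counting overestimates $P$ by up to $\sqrt{2}$ on
  diagonal edges and systematically depresses circularity; Crofton is the
  standard low-bias estimator and matches what mainstream image-analysis
  toolkits compute.
- circularity $= \min(1,\; 4\pi A/P^2)$. The clamp absorbs the small-object
  bias of the Crofton estimator (a single pixel would otherwise exceed 1).
- the moment-equivalent ellipse: the $2\times2$ covariance of pixel
  coordinates, with $1/12$ added to both diagonal terms (each pixel modelled
  as a unit square), eigen-decomposed; axis lengths are $4\sqrt{\lambda}$
  and the aspect ratio is their quotient. The $1/12$ correction makes single
  pixels ($AR = 1$) and 1-px lines well defined, and makes an axis-aligned
  solid $w \times h$ rectangle come out at exactly $\max(w,h)/\min(w,h)$.

Per-cell summaries are **unweighted means over particles**; condition
summaries are unweighted means ± sample SD over cells; condition contrasts
are two-sided Welch $t$-tests on per-cell values with star coding
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, each comparison on its own —
no multiplicity correction, matching the per-comparison star convention of
this assay family). Averaging per cell first (rather than pooling all
particles of a condition) keeps large cells from dominating and matches the
"n cells quantified per condition" design; it is also the choice that makes
the two segmentation modes comparable. Welch rather than Student is the
robust default since nothing guarantees equal variances between conditions;
`statsParams(test = "student")` toggles the pooled test.

## Segmentation

The automatic mode reconstructs a per-cell mask from the nucleus and
membrane channels with a deliberately parameter-light chain:

1. **Nuclei** — Gaussian smoothing (`nucleus_smooth_sigma_px`, default 2),
   global Otsu threshold, hole filling, area filter
   (`nucleus_min_area_px`, default 200 px), then a distance-transform
   watershed whose tolerance (`split_h_maxima_depth`, default 2 px) is the
   h-maxima depth that decides when touching nuclei are split. A constant
   plane has no Otsu threshold and yields zero nuclei.
2. **Cell support** — Otsu on the *log* of the smoothed membrane + mito
   composite. The composite histogram is trimodal (background, dim
   cytoplasm, bright membrane ridge); on the linear scale Otsu separates
   ridge from everything else, on the log scale it separates background
   from cytoplasm, which is the support we want. The support is then eroded
   by the smoothing sigma, because smoothing a bright boundary band dilates
   the foreground outward by roughly sigma; the erosion puts the cell edge
   back at the ridge centre.
3. **Cells** — seeded growth from the nucleus labels over the smoothed
   membrane elevation restricted to the support (EBImage `propagate`), so
   membrane-bright ridges become basin boundaries. Exactly one region per
   nucleus, regions disjoint, each containing its seed.
4. **Filtering** — cells under `cell_min_area_px` (default 2000 px) and,
   by default, cells touching the image border are removed
   (`border_policy = "exclude"`): a truncated cell truncates its network
   and biases both descriptors. Labels are never renumbered by filtering.

Thresholds are global per image (or per cell, below): the imaging model and
the intended acquisitions are single-plane monolayer fields with fairly
uniform illumination, so no illumination-correction stage is included.

In semi-manual mode a label TIFF (0 = background) replaces stages 1–3;
ImageJ ROI archives are not parsed — a label image is the simplest lossless
interchange and is what the bundled simulator writes.

## Binarization and particle analysis

The mitochondrial plane is background-subtracted with a grayscale **white
top-hat** (square structuring element, radius `tophat_radius_px`, default
8 px — about twice the apparent tubule width, so tubules pass and slowly
varying background is removed; the square element makes the operation
separable and exact). The Otsu threshold is then computed **per cell over
that cell's own pixels**, making the descriptor set invariant to
image-wide intensity rescaling and robust to cell-to-cell staining
differences; a constant-intensity cell has no threshold and contributes an
empty mask with a warning.

Particles are connected components under `connectivity` 8 (ImageJ's
default; 4 available), with components below `min_particle_area_px`
(default 4 px) dropped as shot-noise specks. A component straddling a cell
boundary is assigned to the cell holding the majority of its pixels (ties
break to the smaller label); particles are never split across cells.
Labelling order is fixed to the column-major position of each component's
first pixel, so outputs are bit-reproducible regardless of algorithm.

## The synthetic model: what it emulates, and what not

Scenes emulate sub-confluent keratinocyte-like fields: 5–30 cells of
radius 15–25 µm, nucleus stain, membrane-bright cell boundaries over dim
cytoplasm, and a mitochondrial channel spanning tubular-to-punctate
morphologies. Defaults (`sceneParams()`):

- field 1024×1024 px at 0.2 µm/px (a ~205 µm field, the native pixel scale
  of a high-NA confocal); 10 cells fully interior (border cells can be
  added explicitly for testing the border filter);
- cell outlines are star-convex: $r(\theta) = R\,(1 + \sum_{k=2}^{4} a_k
  \cos(k\theta + \phi_k))$ with amplitudes up to 0.05 — smooth, mildly
  irregular shapes that cannot overlap ambiguously; nuclei are ellipses
  with semi-major axis 0.28–0.40 R;
- the mitochondrial skeleton per cell is a set of smoothed random-walk
  polylines (step 2 px, heading noise SD 0.3 rad) confined to the
  cytoplasm, mutually separated by at least one tubule width plus 3 px so
  that ground-truth fragments stay resolvable as distinct particles;
- fragmentation $f \in [0,1]$ sets the fragment count
  $n = \mathrm{round}(2 + 38f)$ at fixed total skeleton length
  (`skeleton_length_budget_um`, default 15 µm), so the mean fragment
  length interpolates from two ~7.5 µm tubules ($f=0$, optionally branched
  with probability `branch_prob`·(1−f), default 0.15 at $f=0$) down to
  ~0.4 µm puncta ($f=1$). Fragment lengths are Gamma-distributed and
  rescaled so the per-cell total equals the budget exactly;
- `tubule_width_um` (default 1.0 µm) is the *apparent* (diffraction-
  broadened) tubule width. The width and length budget were chosen jointly,
  before any validation run, so that the two ends of the $f$ axis realise
  the phenotypes the model must span: at $f=1$ fragments must be near-
  circular puncta comfortably above the 4-px particle floor, and at $f=0$
  long tubules with aspect ratio well above 3. A much larger budget at
  fixed width cannot produce puncta at any $f$ — the fragments would remain
  rods — which is why the default budget is modest; it is a shape-regime
  parameter of a 2-D cartoon, not an estimate of mitochondrial mass.

Rendering (`opticsParams()`): Gaussian PSF (`psf_sigma_px`, default 1.2 px
≈ 0.24 µm, a realistic confocal PSF sigma), scaling to `photon_scale`
(default 200 counts at unit intensity), Poisson shot noise, Gaussian read
noise (SD 3 counts) and a constant offset (10 counts). Geometry and optics
use separate seeds so one scene can be re-imaged under different noise.

The generator validates operators; it does **not** photorealistically mimic
real acquisitions. It omits photobleaching, chromatic shift, cell motion,
intracellular texture, z-structure and illumination gradients. Passing its
tests demonstrates that the operators recover known geometry under blur and
shot noise — not that segmentation would survive, say, strongly uneven
illumination or densely confluent monolayers.

## Validation design

The test suite validates end to end against ground truth, at the default
study conditions (30 cells per condition, pooled over consecutive-seed
fields, ~3–4 fields per condition):

- **descriptor exactness** — analytic identities (circle, square,
  rectangles) and an exhaustive sweep of every 4-connected mask on a
  3×4 grid against a brute-force covariance oracle (tolerance 1e-9);
  Crofton values are frozen against an independent reference
  implementation;
- **monotone fragmentation response** — across
  $f \in \{0, 0.25, 0.5, 0.75, 1\}$ condition-mean circularity must be
  strictly increasing and aspect ratio strictly decreasing;
- **parameter recovery** — pipeline condition means within 15 % of the
  ground-truth oracle (same descriptor operators on noiseless ground-truth
  masks) at $f \in \{0, 0.5, 1\}$ under default optics;
- **mode concordance** — ground-truth cell masks versus automatic
  segmentation on the same rendered fields agree within 10 % on condition
  means;
- **headline significance** — control ($f=0.15$) versus fragmented
  ($f=0.75$), 30 cells each: Welch p ≤ 0.001 for both descriptors, with the
  correct directions;
- **determinism** — identical seeds give byte-identical TIFFs, JSONs and
  CSVs.

`scripts/acceptance.R` re-runs the headline experiment from scratch and
reports the two p-values.

## Numerical choices and degenerate inputs

- Otsu is computed on a 256-bin histogram over the data range; a
  (near-)constant input returns no threshold (empty foreground, with a
  warning where a cell is affected). Foreground is strictly above the
  threshold.
- Grayscale morphology uses a square structuring element with running
  min/max passes; borders pad with ±∞, i.e. the element is cropped at the
  edge.
- The watershed tolerance (h-maxima depth) defaults to 2 px: nuclei whose
  distance-transform peaks differ by less are merged.
- Circularity is clamped at 1; aspect ratio is finite for any non-empty
  pixel set thanks to the 1/12 moment correction.
- Cell placement is rejection sampling with whole-field restarts; an
  impossible packing raises a classed error rather than looping forever.
  `round(2 + 38f)` follows R's round-half-to-even at the $f$ values where
  it matters.
- Welch p-values from degenerate identical groups are reported as
  t = 0, p = 1 ("ns") rather than NaN.
- Coordinates are 0-based (row, col) in all reported centroids, with pixel
  centres at integers; channel-to-plane mapping in configs uses 1-based
  plane indices, the R convention.
- CSV floats are written at 6 significant digits; this is the only
  precision loss on any round trip (label and image TIFFs round-trip
  losslessly).

## Known limitations

- 2-D only: single-plane fields; no z-stacks, time-lapse or tracking.
- The per-comparison t-tests treat cells as independent; donor or
  experiment structure (repeated fields from the same culture) is not
  modelled. With real multi-donor data a hierarchical model would be the
  statistically safer choice.
- Descriptors are limited to circularity and aspect ratio; skeleton-based
  network metrics (branch length, junction counts) are out of scope.
- Absolute descriptor values depend on optics and binarization; they are
  comparable within a configuration, not across instruments. The assay's
  value is in contrasts between conditions, which is what the statistics
  module reports.
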