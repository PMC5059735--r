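#' Segmentation parameters
#'
#' Tunable parameters for nucleus and cell segmentation. Areas are in
#' pixels, sigmas in pixels.
#'
#' @param nucleus_smooth_sigma_px Gaussian sigma applied to the nucleus
#'   plane before thresholding (default 2).
#' @param nucleus_min_area_px minimum nucleus area retained (default 200).
#' @param split_h_maxima_depth h-maxima depth (watershed tolerance) used to
#'   split touching nuclei on the distance transform (default 2).
#' @param cell_min_area_px minimum cell area retained (default 2000).
#' @param border_policy \code{"exclude"} drops cells touching the image
#'   border (default), \code{"keep"} retains them.
#' @param support_smooth_sigma_px Gaussian sigma used to smooth the
#'   membrane plane (watershed elevation) and the membrane+mito composite
#'   that defines the cytoplasmic foreground support (default 2).
#' @return A validated parameter list of class \code{SegmentationParams}.
#' @export
#' @examples
#' segmentationParams(cell_min_area_px = 500)
segmentationParams <- function(nucleus_smooth_sigma_px = 2.0,
                               nucleus_min_area_px = 200,
                               split_h_maxima_depth = 2.0,
                               cell_min_area_px = 2000,
                               border_policy = c("exclude", "keep"),
                               support_smooth_sigma_px = 2.0) {
  border_policy <- match.arg(border_policy)
  stopifnot(nucleus_smooth_sigma_px >= 0, support_smooth_sigma_px >= 0,
            nucleus_min_area_px > 0, cell_min_area_px > 0,
            split_h_maxima_depth >= 0)
  structure(list(
    nucleus_smooth_sigma_px = nucleus_smooth_sigma_px,
    nucleus_min_area_px = nucleus_min_area_px,
    split_h_maxima_depth = split_h_maxima_depth,
    cell_min_area_px = cell_min_area_px,
    border_policy = border_policy,
    support_smooth_sigma_px = support_smooth_sigma_px
  ), class = c("SegmentationParams", "list"))
}

#' Morphology (particle analysis) parameters
#'
#' @param tophat_radius_px radius of the square structuring element of the
#'   white top-hat background subtraction applied to the mitochondrial plane
#'   (default 8; the element spans \code{2*radius+1} pixels).
#' @param min_particle_area_px connected components smaller than this are
#'   discarded as noise specks (default 4).
#' @param connectivity pixel connectivity for particle labelling, 4 or 8
#'   (default 8, the ImageJ convention).
#' @return A validated parameter list of class \code{MorphologyParams}.
#' @export
#' @examples
#' morphologyParams(connectivity = 4)
morphologyParams <- function(tophat_radius_px = 8,
                             min_particle_area_px = 4,
                             connectivity = 8) {
  stopifnot(tophat_radius_px > 0, min_particle_area_px >= 1,
            connectivity %in% c(4, 8))
  structure(list(
    tophat_radius_px = as.integer(tophat_radius_px),
    min_particle_area_px = as.integer(min_particle_area_px),
    connectivity = as.integer(connectivity)
  ), class = c("MorphologyParams", "list"))
}

#' Synthetic scene parameters
#'
#' Geometry of a simulated field. The fragmentation parameter \code{f}
#' interpolates the mitochondrial network from a hyperfused state (f = 0: a
#' couple of long, optionally branched tubules per cell) to a fully
#' fragmented state (f = 1: many short punctate fragments). The expected
#' fragment count per cell is \code{round(2 + 38 f)} and the total skeleton
#' length per cell always equals \code{skeleton_length_budget_um}, so
#' fragmentation shortens fragments rather than destroying mitochondrial
#' material.
#'
#' @param image_size_px field size (height, width) in pixels
#'   (default c(1024, 1024)).
#' @param n_cells number of cells placed fully inside the field (default 10).
#' @param n_border_cells additional cells deliberately clipped by the image
#'   border (default 0); useful for testing border filtering.
#' @param cell_radius_um range (min, max) of mean cell radius in um
#'   (default c(15, 25)).
#' @param f fragmentation parameter in [0, 1].
#' @param skeleton_length_budget_um total mitochondrial skeleton length per
#'   cell in um (default 15).
#' @param branch_prob probability that a tubule carries a side branch in the
#'   fully fused state (f = 0); scales linearly to 0 at f = 1 (default 0.15).
#' @param tubule_width_um rendered (apparent) tubule width in um
#'   (default 1.0).
#' @param pixel_size_um micrometers per pixel (default 0.2).
#' @param seed geometry seed (default 1).
#' @return A validated parameter list of class \code{SceneParams}.
#' @seealso [makeScene()]
#' @export
#' @examples
#' sceneParams(f = 0.75, n_cells = 5, seed = 7)
sceneParams <- function(image_size_px = c(1024L, 1024L),
                        n_cells = 10,
                        n_border_cells = 0,
                        cell_radius_um = c(15, 25),
                        f = 0,
                        skeleton_length_budget_um = 15,
                        branch_prob = 0.15,
                        tubule_width_um = 1.0,
                        pixel_size_um = 0.2,
                        seed = 1) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  stopifnot(f >= 0, f <= 1, skeleton_length_budget_um > 0, n_cells >= 1,
            length(cell_radius_um) == 2L, cell_radius_um[1] > 0,
            cell_radius_um[2] >= cell_radius_um[1], tubule_width_um > 0,
            pixel_size_um > 0, branch_prob >= 0, branch_prob <= 1,
            n_border_cells >= 0)
  structure(list(
    image_size_px = as.integer(image_size_px),
    n_cells = as.integer(n_cells),
    n_border_cells = as.integer(n_border_cells),
    cell_radius_um = as.numeric(cell_radius_um),
    f = as.numeric(f),
    skeleton_length_budget_um = as.numeric(skeleton_length_budget_um),
    branch_prob = as.numeric(branch_prob),
    tubule_width_um = as.numeric(tubule_width_um),
    pixel_size_um = as.numeric(pixel_size_um),
    seed = as.integer(seed)
  ), class = c("SceneParams", "list"))
}

#' Optics and noise parameters for the synthetic renderer
#'
#' Imaging model applied to a ground-truth scene: Gaussian PSF blur,
#' intensity scaling to photon counts, Poisson shot noise, additive Gaussian
#' read noise and a constant camera offset.
#'
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1.2).
#' @param photon_scale expected photon count at unit (peak) structure
#'   intensity (default 200).
#' @param gaussian_read_sd read-noise standard deviation in counts
#'   (default 3).
#' @param background_offset constant offset in counts (default 10).
#' @param seed optics seed; \code{NULL} derives one from the scene's
#'   geometry seed so re-rendering the same scene is deterministic.
#' @return A validated parameter list of class \code{OpticsNoiseParams}.
#' @seealso [renderScene()]
#' @export
#' @examples
#' opticsParams(psf_sigma_px = 0, photon_scale = 0, gaussian_read_sd = 0)
opticsParams <- function(psf_sigma_px = 1.2,
                         photon_scale = 200,
                         gaussian_read_sd = 3,
                         background_offset = 10,
                         seed = NULL) {
  stopifnot(psf_sigma_px >= 0, photon_scale >= 0, gaussian_read_sd >= 0,
            background_offset >= 0)
  structure(list(
    psf_sigma_px = psf_sigma_px,
    photon_scale = photon_scale,
    gaussian_read_sd = gaussian_read_sd,
    background_offset = background_offset,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = c("OpticsNoiseParams", "list"))
}

#' Statistics parameters
#'
#' @param test \code{"welch"} (default, unequal-variance t-test) or
#'   \code{"student"} (pooled-variance).
#' @param star_thresholds p-value thresholds for one, two and three stars
#'   (default \code{c(0.05, 0.01, 0.001)}).
#' @return A validated parameter list of class \code{StatsParams}.
#' @export
statsParams <- function(test = c("welch", "student"),
                        star_thresholds = c(0.05, 0.01, 0.001)) {
  test <- match.arg(test)
  stopifnot(length(star_thresholds) == 3L,
            all(diff(star_thresholds) < 0), all(star_thresholds > 0))
  structure(list(test = test, star_thresholds = star_thresholds),
            class = c("StatsParams", "list"))
}

#' Default pipeline configuration
#'
#' Full configuration tree used by [analyzeImage()], [analyzeBatch()] and
#' the command-line tool, combining channel mapping, pixel size and the
#' parameter blocks of every stage. [readConfig()] merges a YAML file over
#' these defaults.
#'
#' @return Nested list with entries \code{channel_map} (1-based plane
#'   indices by role), \code{pixel_size_um}, \code{segmentation},
#'   \code{morphology}, \code{stats}, \code{synthetic}, \code{optics},
#'   \code{seed}.
#' @export
#' @examples
#' cfg <- defaultConfig()
#' cfg$morphology$connectivity
defaultConfig <- function() {
  list(
    channel_map = list(nucleus = 1L, membrane = 2L, mito = 3L),
    pixel_size_um = 0.2,
    segmentation = unclass(segmentationParams()),
    morphology = unclass(morphologyParams()),
    stats = unclass(statsParams()),
    synthetic = unclass(sceneParams()),
    optics = unclass(opticsParams()),
    seed = 1L
  )
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected at the top level; provided keys override the
#' defaults of [defaultConfig()] recursively.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return configuration list as in [defaultConfig()].
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stopc("mitomorph_error_missing_file", "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stopc("mitomorph_error_config", "unknown config key(s): %s",
          paste(bad, collapse = ", "))
  mergeConfig(cfg, user)
}

## Re-validate config sub-blocks through their constructors.
configSegParams <- function(cfg) do.call(segmentationParams, cfg$segmentation)
configMorphParams <- function(cfg) do.call(morphologyParams, cfg$morphology)
configStatsParams <- function(cfg) do.call(statsParams, cfg$stats)
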