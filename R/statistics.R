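## statistics: condition summaries and significance reporting.
##
## The unit of analysis is the cell: per-cell descriptor means are averaged
## (unweighted) into condition means with sample SD, and conditions are
## compared with a two-sided t-test (Welch by default). Stars follow the
## usual coding: * p < 0.05, ** p < 0.01, *** p < 0.001. No multiple-testing
## correction is applied: each comparison against the control is reported on
## its own, matching the per-comparison star convention of the read-out this
## package reproduces.

#' Summarize one condition over its cells
#'
#' Unweighted mean and sample SD (n - 1 denominator) of the per-cell mean
#' circularity and aspect ratio. With a single cell the SDs are reported as
#' \code{NA}.
#'
#' @param cells per-cell data frame (see [summarizeCells()]) with columns
#'   \code{mean_circularity} and \code{mean_aspect_ratio}.
#' @param label condition label.
#' @return One-row \code{data.frame}: \code{condition}, \code{n_cells},
#'   \code{mean_circularity}, \code{sd_circularity},
#'   \code{mean_aspect_ratio}, \code{sd_aspect_ratio}.
#' @export
#' @examples
#' summarizeCondition(data.frame(mean_circularity = c(0.5, 0.7),
#'   mean_aspect_ratio = c(2, 3)), "control")
summarizeCondition <- function(cells, label) {
  if (nrow(cells) == 0L)
    stopc("mitomorph_error_empty_condition",
          "condition '%s' has no cells", label)
  sdOrNA <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
  data.frame(
    condition = label,
    n_cells = nrow(cells),
    mean_circularity = mean(cells$mean_circularity),
    sd_circularity = sdOrNA(cells$mean_circularity),
    mean_aspect_ratio = mean(cells$mean_aspect_ratio),
    sd_aspect_ratio = sdOrNA(cells$mean_aspect_ratio))
}

#' Star coding of a p-value
#'
#' Pure function of the p-value and the three thresholds:
#' \code{"***"} below the third threshold, \code{"**"} below the second,
#' \code{"*"} below the first, \code{"ns"} otherwise.
#'
#' @param p p-value(s).
#' @param thresholds decreasing vector of three thresholds
#'   (default \code{c(0.05, 0.01, 0.001)}).
#' @return Character vector over \code{c("ns", "*", "**", "***")}.
#' @export
#' @examples
#' pStars(c(0.04, 0.009, 0.0005, 0.2))
pStars <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) < 0))
  ifelse(p < thresholds[3], "***",
    ifelse(p < thresholds[2], "**",
      ifelse(p < thresholds[1], "*", "ns")))
}

#' Compare one descriptor between two groups of cells
#'
#' Two-sided t-test on per-cell descriptor values; Welch (unequal-variance)
#' by default, pooled-variance Student's optionally. Identical groups give
#' t = 0, p = 1, "ns".
#'
#' @param groupA,groupB numeric vectors of per-cell descriptor values, or
#'   per-cell data frames from which \code{descriptor} is taken.
#' @param descriptor descriptor name (column name when data frames are
#'   passed; label otherwise), e.g. \code{"mean_circularity"}.
#' @param labels length-2 character vector of group labels.
#' @param params a [statsParams()] list.
#' @return One-row \code{data.frame}: \code{descriptor}, \code{group_a},
#'   \code{group_b}, \code{n_a}, \code{n_b}, \code{mean_a}, \code{mean_b},
#'   \code{t}, \code{df}, \code{p}, \code{stars}.
#' @export
#' @examples
#' compareGroups(rnorm(30), rnorm(30) + 2, "mean_circularity")
compareGroups <- function(groupA, groupB, descriptor = "descriptor",
                          labels = c("A", "B"), params = statsParams()) {
  pick <- function(g) if (is.data.frame(g)) g[[descriptor]] else g
  a <- pick(groupA); b <- pick(groupB)
  if (length(a) < 2L || length(b) < 2L)
    stopc("mitomorph_error_group_too_small",
          "each group needs at least 2 cells (got %d and %d)",
          length(a), length(b))
  if (isTRUE(all.equal(c(a, b), rep(mean(c(a, b)), length(a) + length(b))))) {
    tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
               p.value = 1)
  } else {
    tt <- t.test(a, b, var.equal = (params$test == "student"))
  }
  p <- as.numeric(tt$p.value)
  data.frame(
    descriptor = descriptor, group_a = labels[1], group_b = labels[2],
    n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b),
    t = as.numeric(tt$statistic), df = as.numeric(tt$parameter), p = p,
    stars = pStars(p, params$star_thresholds))
}

#' Dose-response comparison table against the control condition
#'
#' One comparison per non-control condition and descriptor (circularity and
#' aspect ratio), taking the first element as the control — the layout used
#' to report dose-dependent mitochondrial fragmentation.
#'
#' @param cellsByCondition named list of per-cell data frames (see
#'   [summarizeCells()]), ordered by dose with the control first.
#' @param params a [statsParams()] list.
#' @return \code{data.frame} of [compareGroups()] rows.
#' @export
doseResponseTable <- function(cellsByCondition, params = statsParams()) {
  if (length(cellsByCondition) < 2L)
    stopc("mitomorph_error_too_few_conditions",
          "need at least 2 conditions (control first)")
  labs <- names(cellsByCondition)
  if (is.null(labs)) labs <- paste0("condition", seq_along(cellsByCondition))
  ctrl <- cellsByCondition[[1]]
  out <- list()
  for (i in seq_along(cellsByCondition)[-1]) {
    for (d in c("mean_circularity", "mean_aspect_ratio")) {
      out[[length(out) + 1L]] <- compareGroups(
        ctrl, cellsByCondition[[i]], d, labels = labs[c(1L, i)],
        params = params)
    }
  }
  do.call(rbind, out)
}
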