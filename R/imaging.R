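## Low-level raster primitives shared by segmentation and morphology.

## Gaussian smoothing; sigma = 0 is the identity.
smoothPlane <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

## Otsu threshold on a numeric vector: maximises between-class variance on a
## 256-bin histogram over the data range. Returns NA for (near-)constant
## input where no threshold exists. Foreground is `value > threshold`.
otsuThreshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  lo <- min(values); hi <- max(values)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) return(NA_real_)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(values, breaks, all.inside = TRUE),
                           nbins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bc <- w1 * w2 * (m1 - m2)^2
  bc[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(bc)
  breaks[k + 1L]
}

## Separable grayscale erosion/dilation with a (2r+1)^2 square structuring
## element, done as running min/max along rows then columns. Border handling
## pads with +Inf (erosion) / -Inf (dilation), i.e. the element is cropped
## at the image edge.
runExtreme <- function(m, r, op) {
  pad <- if (identical(op, pmin)) Inf else -Inf
  n <- nrow(m); p <- ncol(m)
  big <- matrix(pad, n + 2L * r, p)
  big[(r + 1L):(r + n), ] <- m
  acc <- m
  for (k in seq_len(2L * r + 1L) - 1L)
    acc <- op(acc, big[(1L + k):(n + k), , drop = FALSE])
  m2 <- acc
  big2 <- matrix(pad, n, p + 2L * r)
  big2[, (r + 1L):(r + p)] <- m2
  acc <- m2
  for (k in seq_len(2L * r + 1L) - 1L)
    acc <- op(acc, big2[, (1L + k):(p + k), drop = FALSE])
  acc
}

grayErode <- function(m, r) runExtreme(m, r, pmin)
grayDilate <- function(m, r) runExtreme(m, r, pmax)

## White top-hat: image minus its grayscale opening. Removes any background
## structure wider than the (2r+1)-pixel square element while keeping
## narrow bright features (mitochondria) intact.
grayTopHat <- function(m, r) m - grayDilate(grayErode(m, r), r)

## Connected-component labelling with 4- or 8-connectivity (EBImage's
## bwlabel is 4-connected only, so the 8-connected case — the ImageJ
## default — is a vectorised frontier flood fill). Labels are assigned in
## column-major order of each component's first pixel, so the result is
## deterministic and independent of the underlying algorithm.
labelConnected <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  mode(mask) <- "logical"
  n <- nrow(mask); p <- ncol(mask)
  if (!any(mask)) return(matrix(0L, n, p))
  if (connectivity == 4L)
    return(relabelRaster(matrix(as.integer(EBImage::bwlabel(mask)), n, p)))
  lab <- matrix(0L, n, p)
  nxt <- 0L
  neighbours <- function(idx) {
    r <- ((idx - 1L) %% n) + 1L
    up <- r > 1L; dn <- r < n
    lf <- idx > n; rt <- idx <= n * (p - 1L)
    c(idx[up] - 1L, idx[dn] + 1L, idx[lf] - n, idx[rt] + n,
      idx[up & lf] - 1L - n, idx[dn & lf] + 1L - n,
      idx[up & rt] - 1L + n, idx[dn & rt] + 1L + n)
  }
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      nb <- unique(neighbours(frontier))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  relabelRaster(lab)
}

## Renumber labels 1..K by column-major position of first occurrence.
relabelRaster <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

## Pixel areas per label id (named integer vector).
labelAreas <- function(lab) {
  ids <- lab[lab > 0L]
  if (!length(ids)) return(stats::setNames(integer(0), character(0)))
  t <- tabulate(ids)
  keep <- which(t > 0L)
  stats::setNames(t[keep], keep)
}
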