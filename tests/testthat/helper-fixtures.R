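## Shared fixtures: small fast scenes and independent oracles.

## Compact field used by module tests (3 small cells in a 360 px field);
## the acceptance tests use the full default conditions instead.
smallScene <- function(f = 0.5, seed = 1, n_cells = 3, n_border = 0,
                       image = 360) {
  makeScene(sceneParams(n_cells = n_cells, n_border_cells = n_border,
                        cell_radius_um = c(8, 11), image_size_px = image,
                        f = f, seed = seed))
}

## effectively noise-free imaging (very high photon count, no read noise)
cleanOptics <- function(psf = 1.2, seed = 1) {
  opticsParams(psf_sigma_px = psf, photon_scale = 5000,
               gaussian_read_sd = 0, background_offset = 0, seed = seed)
}

smallConfig <- function() {
  cfg <- defaultConfig()
  cfg$synthetic$n_cells <- 3L
  cfg$synthetic$cell_radius_um <- c(8, 11)
  cfg$synthetic$image_size_px <- c(360L, 360L)
  cfg$segmentation$cell_min_area_px <- 1000
  cfg
}

discMask <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) out[i, ] <- (i - ctr)^2 + (seq_len(n) - ctr)^2 <= r^2
  out
}

maskCoords <- function(mask) which(mask, arr.ind = TRUE)

## Independent moment oracle: raw accumulation loops + LAPACK eigenvalues
## (the implementation under test uses vectorised sums and a closed-form
## quadratic instead).
bruteAxes <- function(coords) {
  n <- nrow(coords)
  mr <- sum(coords[, 1]) / n
  mc <- sum(coords[, 2]) / n
  srr <- scc <- src <- 0
  for (i in seq_len(n)) {
    srr <- srr + (coords[i, 1] - mr)^2
    scc <- scc + (coords[i, 2] - mc)^2
    src <- src + (coords[i, 1] - mr) * (coords[i, 2] - mc)
  }
  C <- matrix(c(srr / n + 1 / 12, src / n, src / n, scc / n + 1 / 12), 2, 2)
  ev <- eigen(C, symmetric = TRUE)$values
  4 * sqrt(ev)
}

## Closed-form Welch test, independent of stats::t.test.
bruteWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## All non-empty 4-connected pixel sets on an h x w grid.
connectedSubsets4 <- function(h, w) {
  out <- list()
  for (bits in seq_len(2^(h * w) - 1)) {
    v <- as.logical(bitwAnd(bits, 2^(seq_len(h * w) - 1)))
    m <- matrix(v, h, w)
    ## flood fill from first pixel; 4-connected iff everything reached
    idx <- which(m)
    seen <- idx[1]
    frontier <- idx[1]
    while (length(frontier)) {
      nb <- c(frontier - 1, frontier + 1, frontier - h, frontier + h)
      r <- ((frontier - 1) %% h) + 1
      nb <- nb[c(r > 1, r < h, frontier > h, frontier <= h * (w - 1))]
      nb <- setdiff(nb[nb %in% idx], seen)
      seen <- c(seen, nb)
      frontier <- nb
    }
    if (length(seen) == length(idx)) out[[length(out) + 1L]] <- m
  }
  out
}
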