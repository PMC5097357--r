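# Metal-trace segmentation on projection data ---------------------------------

new_metal_mask <- function(values, stage) {
  storage.mode(values) <- "double"
  structure(list(values = values, stage = stage), class = "metal_mask")
}

#' @export
print.metal_mask <- function(x, ...) {
  cat(sprintf("metal_mask (%s): %d x %d, %d metal pixels (metal = 0)\n",
              x$stage, nrow(x$values), ncol(x$values), sum(x$values == 0)))
  invisible(x)
}

mask_values <- function(mask) {
  if (inherits(mask, "metal_mask")) mask$values else mask
}

#' Global-threshold seed mask
#'
#' Marks metal on projection data with a single threshold: mask value 0
#' (metal) where the projection value is \code{>= T}, 1 elsewhere. For
#' peak-normalized attenuation data the threshold is a fraction of the peak
#' value.
#'
#' @param sino a \code{sinogram} or numeric matrix.
#' @param T threshold, strictly inside (0, 1) for normalized data.
#' @return a \code{metal_mask} of stage \code{"seed"} (metal = 0 convention).
#' @export
global_threshold_mask <- function(sino, T) {
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  if (T <= 0 || T >= 1) stop("global threshold must lie strictly in (0, 1)")
  new_metal_mask((vals < T) * 1, "seed")
}

#' Islands of metal in one view
#'
#' Finds the islands of zeroes (metal runs) along the detector axis s within
#' one view of a seed mask.
#'
#' @param mask a \code{metal_mask} (or 0/1 matrix), metal = 0.
#' @param view view (column) index.
#' @return list of islands, each \code{list(s1, s2)} with 1-based inclusive
#'   detector indices; empty list if the view has no metal.
#' @export
find_islands <- function(mask, view) {
  col <- mask_values(mask)[, view]
  r <- rle(col == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) list(s1 = starts[i], s2 = ends[i]))
}

#' Per-island intensity statistics
#'
#' Standard deviation (population convention, N divisor), maximum and minimum
#' of the original projection values over an island's pixels.
#'
#' @param sino a \code{sinogram} or numeric matrix the island indexes into.
#' @param island \code{list(s1, s2)} as returned by \code{\link{find_islands}}.
#' @param view view (column) index the island belongs to.
#' @return \code{list(sigma, A, B)} with \code{A} the maximum and \code{B}
#'   the minimum intensity.
#' @export
island_statistics <- function(sino, island, view) {
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  v <- vals[island$s1:island$s2, view]
  n <- length(v)
  sigma <- sqrt(sum((v - mean(v))^2) / n)
  list(sigma = sigma, A = max(v), B = min(v))
}

# One expansion pass along the rows of `vals` (runs within each column):
# from each island boundary, walk outward while the values stay inside the
# island's acceptance band, at most W steps.
expand_pass <- function(vals, seed, W, a) {
  out <- seed
  n_s <- nrow(vals)
  for (v in seq_len(ncol(vals))) {
    col_seed <- seed[, v]
    r <- rle(col_seed == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      s1 <- starts[i]; s2 <- ends[i]
      y <- vals[s1:s2, v]
      m <- mean(y)
      sigma <- sqrt(sum((y - m)^2) / length(y))
      lo <- min(y) - a * sigma
      hi <- max(y) + a * sigma
      k <- s1 - 1L
      while (k >= max(1L, s1 - W) && vals[k, v] >= lo && vals[k, v] <= hi) {
        out[k, v] <- 0
        k <- k - 1L
      }
      k <- s2 + 1L
      while (k <= min(n_s, s2 + W) && vals[k, v] >= lo && vals[k, v] <= hi) {
        out[k, v] <- 0
        k <- k + 1L
      }
    }
  }
  out
}

#' Adaptive local-threshold expansion of a seed mask
#'
#' Refines a global-threshold seed using local island statistics: a boundary
#' search for the exact extent of each metallic object. For each island of
#' zeroes the projection values inside the island give its minimum \code{B},
#' maximum \code{A} and standard deviation \code{sigma}; starting at the
#' island's end points \code{s1} and \code{s2}, the mask grows outward, one
#' pixel at a time and at most \code{W} detector bins, for as long as the
#' pixel intensity stays inside the acceptance band
#' \code{[B - a*sigma, A + a*sigma]} (inclusive at both edges). The band
#' widens the island's observed intensity range by \code{a*sigma} on each
#' side: when a metal region overlaps dense anatomy, \code{B} (and with it
#' the lower band edge) rises, which keeps the segmented region from growing
#' too much. The final metal set is the union of the seed metal set and all
#' accepted pixels, so expansion never removes seed pixels. Windows reaching
#' past the detector edge are clipped.
#'
#' For 2D sinograms a single pass runs along the detector axis s. For
#' projection images (s, t) a second, vertical pass applies the same rule
#' along t, with island statistics recomputed on the output of the first
#' pass.
#'
#' @param sino the \code{sinogram} (or projection-image matrix) the seed was
#'   derived from.
#' @param seed a \code{metal_mask} of stage \code{"seed"}.
#' @param W search window half-width in detector bins (default 30).
#' @param a scaling factor for the acceptance band (default 2).
#' @param passes \code{"s"} for the horizontal pass only (the 2D sinogram
#'   case, default), or \code{c("s", "t")} for projection images.
#' @return a \code{metal_mask} of stage \code{"expanded"}.
#' @export
adaptive_expand <- function(sino, seed, W = 30L, a = 2,
                            passes = if (inherits(sino, "sinogram")) "s"
                                     else c("s", "t")) {
  if (W < 1L) stop("W must be >= 1")
  if (a <= 0) stop("scaling factor a must be > 0")
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  m <- mask_values(seed)
  if (!all(dim(m) == dim(vals)))
    stop("seed mask is not congruent with the projection data")
  out <- m
  if ("s" %in% passes) out <- expand_pass(vals, out, as.integer(W), a)
  if ("t" %in% passes)
    out <- t(expand_pass(t(vals), t(out), as.integer(W), a))
  out <- pmin(out, m)  # union of metal sets (metal = 0)
  new_metal_mask(out, "expanded")
}

#' Otsu's threshold
#'
#' The histogram threshold maximizing between-class variance, the standard
#' parameter-free split of a bimodal intensity distribution. Used by
#' \code{\link{mar}} to separate the high-attenuation cluster (metal) from
#' tissue in the uncorrected reconstruction when no explicit image-domain
#' threshold is given.
#'
#' @param values numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value (a histogram bin midpoint).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  if (!all(is.finite(v))) stop("values must be finite")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  w1 <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_total <- mu[n_bins]
  sb <- (mu_total * w1 - mu)^2 / (w1 * (1 - w1) + 1e-12)
  h$mids[which.max(sb[-n_bins])]
}

#' Image-domain metal mask
#'
#' Global thresholding of a reconstructed image: pixels with attenuation
#' \code{>= image_T} are metal (mask value 0).
#'
#' @param image a \code{recon_image} or numeric matrix (1/cm).
#' @param image_T attenuation threshold in the image units.
#' @return a \code{metal_mask} on the image grid.
#' @export
image_metal_mask <- function(image, image_T) {
  vals <- if (inherits(image, "recon_image")) image$values else image
  new_metal_mask((vals < image_T) * 1, "seed")
}
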