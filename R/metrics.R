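# Quantitative evaluation: SSIM on ROIs, line profiles, difference images -----

gaussian_kernel_1d <- function(sigma = 1.5, half = 5L) {
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

conv_valid_1d_cols <- function(x, g) {
  k <- length(g)
  n <- nrow(x)
  out <- matrix(0, n - k + 1L, ncol(x))
  for (i in seq_len(k)) out <- out + x[i:(n - k + i), , drop = FALSE] * g[i]
  out
}

conv_valid <- function(x, g) {
  t(conv_valid_1d_cols(t(conv_valid_1d_cols(x, g)), g))
}

ssim_map <- function(x, y, L, K1 = 0.01, K2 = 0.03, sigma = 1.5,
                     half = 5L) {
  g <- gaussian_kernel_1d(sigma, half)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mu1 <- conv_valid(x, g); mu2 <- conv_valid(y, g)
  s11 <- conv_valid(x * x, g) - mu1^2
  s22 <- conv_valid(y * y, g) - mu2^2
  s12 <- conv_valid(x * y, g) - mu1 * mu2
  ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
}

#' Structural similarity on a region of interest
#'
#' Gaussian-windowed SSIM (window standard deviation 1.5 pixels, 11 x 11
#' support, constants K1 = 0.01, K2 = 0.03, following the original reference
#' implementation), averaged over the windows centred at the ROI's pixels.
#' Windows may extend past the ROI into the surrounding image but must fit
#' inside the image; ROI pixels too close to the image border for a full
#' window are skipped. The dynamic range is the reference image's full-image
#' max - min. ROI pixels excluded from the ROI definition (e.g. metal pixels
#' of an annular ROI) contribute no window of their own, although they may
#' still fall inside windows centred on retained pixels.
#'
#' @param img the evaluated image (\code{recon_image} or matrix).
#' @param ref the reference image.
#' @param roi a \code{roi_spec} (or a list of row/col index vectors).
#' @return the mean SSIM over the ROI, a value in [-1, 1].
#' @export
ssim_roi <- function(img, ref, roi) {
  x <- if (inherits(img, "recon_image")) img$values else img
  y <- if (inherits(ref, "recon_image")) ref$values else ref
  if (!all(dim(x) == dim(y))) stop("images are not congruent")
  px <- if (inherits(roi, "roi_spec")) roi$pixels
        else as.matrix(expand.grid(row = roi$rows, col = roi$cols))
  half <- 5L
  ok <- px[, 1] > half & px[, 1] <= nrow(x) - half &
        px[, 2] > half & px[, 2] <= ncol(x) - half
  px <- px[ok, , drop = FALSE]
  if (nrow(px) == 0L)
    stop("no SSIM window fits: every ROI pixel is within the window ",
         "half-width of the image border")
  rr <- range(px[, 1]); cc <- range(px[, 2])
  cx <- x[(rr[1] - half):(rr[2] + half), (cc[1] - half):(cc[2] + half)]
  cy <- y[(rr[1] - half):(rr[2] + half), (cc[1] - half):(cc[2] + half)]
  L <- max(y) - min(y)
  if (L <= 0) L <- 1
  # map of windows centred at rows rr[1]:rr[2], cols cc[1]:cc[2]
  sm <- ssim_map(cx, cy, L)
  mean(sm[cbind(px[, 1] - rr[1] + 1L, px[, 2] - cc[1] + 1L)])
}

#' Pixel intensity profile along a line
#'
#' Samples image values along a line with bilinear interpolation at
#' sub-pixel positions.
#'
#' @param img a \code{recon_image} or matrix.
#' @param line either \code{list(row, cols)} for a horizontal line (row may
#'   be fractional) or \code{list(from = c(row, col), to = c(row, col), n)}.
#' @return numeric vector of sampled values.
#' @export
line_profile <- function(img, line) {
  z <- if (inherits(img, "recon_image")) img$values else img
  if (!is.null(line$row)) {
    rows <- rep(line$row, length(line$cols))
    cols <- line$cols
  } else {
    tt <- seq(0, 1, length.out = line$n)
    rows <- line$from[1] + tt * (line$to[1] - line$from[1])
    cols <- line$from[2] + tt * (line$to[2] - line$from[2])
  }
  if (any(rows < 1 | rows > nrow(z) | cols < 1 | cols > ncol(z)))
    stop("profile line extends outside the image")
  r0 <- pmin(floor(rows), nrow(z) - 1L); fr <- rows - r0
  c0 <- pmin(floor(cols), ncol(z) - 1L); fc <- cols - c0
  z[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    z[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    z[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    z[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Signed difference image with summary norms
#'
#' @param img evaluated image.
#' @param ref reference image.
#' @param exclude optional logical matrix of pixels (e.g. metal) left out of
#'   the summary norms.
#' @return \code{list(values, l1, linf)} where \code{l1} is the mean absolute
#'   difference and \code{linf} the maximum absolute difference over the
#'   non-excluded pixels.
#' @export
difference_image <- function(img, ref, exclude = NULL) {
  x <- if (inherits(img, "recon_image")) img$values else img
  y <- if (inherits(ref, "recon_image")) ref$values else ref
  if (!all(dim(x) == dim(y))) stop("images are not congruent")
  d <- x - y
  keep <- if (is.null(exclude)) rep(TRUE, length(d)) else !as.vector(exclude)
  list(values = d, l1 = mean(abs(d[keep])), linf = max(abs(d[keep])))
}
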