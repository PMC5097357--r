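# Reconstruction: filtered backprojection and SART ----------------------------

# Discrete Ram-Lak filter kernel (spatial domain), in detector-sample units:
# h(0) = 1/4, h(n) = -1/(pi^2 n^2) for odd n, 0 for even n.
ramlak_kernel <- function(n_det) {
  n <- -(n_det - 1):(n_det - 1)
  h <- numeric(length(n))
  h[n == 0] <- 0.25
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2)
  h
}

filter_sinogram <- function(values, window = c("ramp", "hann")) {
  window <- match.arg(window)
  n_det <- nrow(values)
  h <- ramlak_kernel(n_det)
  nfft <- 2^ceiling(log2(length(h) + n_det))
  H <- fft(c(h, numeric(nfft - length(h))))
  if (window == "hann") {
    # apply a Hann rolloff to the frequency response of the discrete kernel
    fr <- seq(0, 1, length.out = nfft / 2 + 1)
    w <- 0.5 * (1 + cos(pi * fr))
    W <- c(w, rev(w[2:(nfft / 2)]))
    H <- H * W
  }
  out <- matrix(0, n_det, ncol(values))
  for (v in seq_len(ncol(values))) {
    p <- c(values[, v], numeric(nfft - n_det))
    q <- Re(fft(fft(p) * H, inverse = TRUE)) / nfft
    out[, v] <- q[n_det:(2 * n_det - 1)]
  }
  out
}

new_recon <- function(values, provenance) {
  structure(list(values = values, provenance = provenance),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("recon_image: %d x %d, range [%.4g, %.4g] (%s)\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              x$provenance$algorithm))
  invisible(x)
}

#' Filtered backprojection
#'
#' Standard parallel-beam FBP: each view is convolved with the discrete
#' ramp (Ram-Lak) kernel, optionally rolled off with a Hann window, then
#' backprojected with linear interpolation. A linear operator; reconstructed
#' values are in 1/cm when the sinogram holds line integrals in cm units.
#'
#' @param sino a \code{sinogram} (parallel-beam geometry).
#' @param filter \code{"ramp"} (default) or \code{"hann"}.
#' @return a \code{recon_image}.
#' @export
fbp <- function(sino, filter = c("ramp", "hann")) {
  stopifnot(inherits(sino, "sinogram"))
  filter <- match.arg(filter)
  g <- sino$geometry
  if (g$mode != "parallel")
    stop("fbp supports parallel-beam geometry; use sart() for fan beam")
  if (nrow(sino$values) != g$n_det || ncol(sino$values) != g$n_views)
    stop("sinogram dimensions do not match its geometry")
  scale <- if (is.null(sino$peak_norm)) 1 else sino$peak_norm
  cm_per_px <- sino$pixel_size_mm / 10
  q <- filter_sinogram(sino$values * scale / cm_per_px, filter)
  bp <- cpp_back_project(q, g$angles, g$det_spacing, g$nx, g$nx)
  # pi / n_views angular weight (for both 180 and 360 degree coverage);
  # the discrete kernel is per detector sample, so divide by the pitch once
  img <- bp * pi / (g$n_views * g$det_spacing)
  new_recon(img, list(algorithm = "fbp", filter = filter))
}

#' Simultaneous algebraic reconstruction technique
#'
#' SART with sequential view ordering: for each view the image receives an
#' additive update of the ray-normalized residuals, backprojected with the
#' same Joseph weights as the forward model and normalized by the per-pixel
#' weight sum. A nonnegativity clamp is applied after every full iteration.
#' Deterministic given the inputs. Reconstruction diverging beyond 10x the
#' initial sweep residual raises an error.
#'
#' @param sino a \code{sinogram} (parallel or fan beam).
#' @param n_iter number of full iterations (default 20).
#' @param relax relaxation factor in (0, 1] (default 0.25).
#' @param init optional initial image (matrix or \code{recon_image});
#'   default zeros.
#' @param nonneg apply the nonnegativity clamp (default \code{TRUE}).
#' @return a \code{recon_image}; \code{provenance$residuals} holds the
#'   per-iteration pre-update sweep residual norms.
#' @export
sart <- function(sino, n_iter = 20L, relax = 0.25, init = NULL,
                 nonneg = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (relax <= 0 || relax > 1) stop("relax must be in (0, 1]")
  g <- sino$geometry
  if (nrow(sino$values) != g$n_det || ncol(sino$values) != g$n_views)
    stop("sinogram dimensions do not match its geometry")
  scale <- if (is.null(sino$peak_norm)) 1 else sino$peak_norm
  cm_per_px <- sino$pixel_size_mm / 10
  x0 <- if (is.null(init)) matrix(0, g$nx, g$nx)
        else if (inherits(init, "recon_image")) init$values else init
  res <- cpp_sart(sino$values * scale / cm_per_px, g$angles, g$det_spacing,
                  g$mode == "fan", g$sod, g$nx, g$nx, as.integer(n_iter),
                  relax, x0, nonneg)
  new_recon(res$image,
            list(algorithm = "sart", n_iter = n_iter, relax = relax,
                 nonneg = nonneg, residuals = res$residuals))
}

#' Data residual of an image against a sinogram
#'
#' L2 norm of the mismatch between the forward projection of an image and
#' projection data; used for convergence diagnostics.
#'
#' @param image a \code{recon_image} or matrix (1/cm).
#' @param sino a \code{sinogram}.
#' @return the residual norm (in the sinogram's working units).
#' @export
data_residual <- function(image, sino) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  img <- if (inherits(image, "recon_image")) image$values else image
  scale <- if (is.null(sino$peak_norm)) 1 else sino$peak_norm
  cpp_data_residual(img, sino$values * scale / (sino$pixel_size_mm / 10),
                    g$angles, g$det_spacing, g$mode == "fan", g$sod)
}
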