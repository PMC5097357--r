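# Full metal artifact reduction pipeline --------------------------------------

#' Prior sinogram
#'
#' Forward projection of the prior image, placed on the same scale as the
#' peak-normalized reference sinogram (division by the reference's stored
#' peak). No further scaling is fitted: the projector is the same ray model
#' that produced the data, so outside the metal trace the prior sinogram is
#' commensurate with the reference by construction.
#'
#' @param prior the prior \code{recon_image} (or matrix, 1/cm).
#' @param reference the (peak-normalized) measured \code{sinogram}.
#' @return a \code{sinogram} congruent with \code{reference}.
#' @export
prior_sinogram <- function(prior, reference) {
  stopifnot(inherits(reference, "sinogram"))
  img <- if (inherits(prior, "recon_image")) prior$values else prior
  ps <- forward_project(img, reference$geometry, reference$pixel_size_mm)
  if (!is.null(reference$peak_norm)) {
    ps$values <- ps$values / reference$peak_norm
    ps$peak_norm <- reference$peak_norm
  }
  ps
}

#' Metal-trace replacement
#'
#' Elementwise multiplexing of original and prior projection data with the
#' metal mask (metal = 0):
#' \code{P_hat = M * P_orig + (1 - M) * P_prior}. Outside the metal trace the
#' output equals the original data bitwise; inside, the prior data.
#'
#' @param P_orig the measured \code{sinogram} (or matrix).
#' @param P_prior the prior \code{sinogram} (or matrix) on the same scale.
#' @param M a \code{metal_mask}.
#' @return the corrected projection data, same type as \code{P_orig}.
#' @export
replace_metal_trace <- function(P_orig, P_prior, M) {
  a <- if (inherits(P_orig, "sinogram")) P_orig$values else P_orig
  b <- if (inherits(P_prior, "sinogram")) P_prior$values else P_prior
  m <- mask_values(M)
  if (!all(dim(a) == dim(b), dim(a) == dim(m)))
    stop("projection data and mask dimensions do not match")
  out <- m * a + (1 - m) * b
  if (inherits(P_orig, "sinogram")) {
    P_orig$values <- out
    P_orig
  } else out
}

#' Final reconstruction with metal fill-back
#'
#' SART reconstruction of the corrected projection data, after which the
#' metal pixels are overwritten from the uncorrected reconstruction so the
#' metallic structures remain visible.
#'
#' @param corrected the corrected \code{sinogram}.
#' @param image_mask a \code{metal_mask} on the image grid (metal = 0).
#' @param uncorrected the uncorrected \code{recon_image}.
#' @param ... passed to \code{\link{sart}}.
#' @return a \code{recon_image}.
#' @export
finalize_image <- function(corrected, image_mask, uncorrected, ...) {
  fin <- sart(corrected, ...)
  m <- mask_values(image_mask)
  unc <- if (inherits(uncorrected, "recon_image")) uncorrected$values
         else uncorrected
  fin$values[m == 0] <- unc[m == 0]
  fin$provenance$fill_back <- sum(m == 0)
  fin
}

#' Metal artifact reduction of a projection data set
#'
#' Runs the full correction pipeline on an attenuation sinogram:
#' peak normalization; metal-trace seed by global thresholding; (proposed
#' mode) adaptive local-threshold expansion; linear in-painting and SART for
#' the streak-free image; metal nullification of the uncorrected SART
#' reconstruction for the metal-free image; fusion of the two into the prior
#' image through the normalized-difference weight map; forward projection of
#' the prior; replacement of the metal trace; final SART reconstruction with
#' metal fill-back.
#'
#' In \code{fp_mar} mode the metal trace stops at the global-threshold seed
#' (no adaptive expansion), reproducing a fusion-prior MAR driven purely by
#' the global threshold.
#'
#' The global \code{threshold} is expressed on the peak-normalized projection
#' data as a transmitted-intensity fraction: a ray is seeded as metal when
#' its transmitted intensity falls to \code{threshold} of the peak
#' (equivalently, when its attenuation line integral reaches
#' \code{-log(threshold)}). Typical values are 0.05--0.07, chosen so that
#' only the metallic objects are segmented.
#'
#' @param sino an attenuation \code{sinogram} (normalized internally).
#' @param mode \code{"proposed"} (default) or \code{"fp_mar"}.
#' @param threshold global threshold in (0, 1) (default 0.05).
#' @param W search window half-width for the expansion (default 30).
#' @param a scaling factor of the acceptance band (default 2).
#' @param p,c fusion weighting parameters (defaults 10 and 0.1).
#' @param n_iter,relax SART settings (defaults 20 and 0.25).
#' @param image_threshold attenuation threshold for the image-domain metal
#'   mask; default \code{NULL} uses \code{\link{otsu_threshold}} of the
#'   uncorrected reconstruction, which separates the high-attenuation
#'   (metal) cluster from tissue without a scale-dependent constant.
#' @param uncorrected optional precomputed uncorrected SART reconstruction of
#'   \code{sino} (reused across runs on the same data).
#' @param keep_intermediates retain all stage outputs (default \code{TRUE}).
#' @return an object of class \code{mar}: list with \code{final} (the
#'   corrected \code{recon_image}), \code{uncorrected}, \code{config},
#'   \code{timings} and (optionally) \code{intermediates} (seed and expanded
#'   masks, in-painted sinogram, streak-free, metal-free and prior images,
#'   weight map, prior and corrected sinograms, image mask).
#' @export
mar <- function(sino, mode = c("proposed", "fp_mar"), threshold = 0.05,
                W = 30L, a = 2, p = 10, c = 0.1, n_iter = 20L, relax = 0.25,
                image_threshold = NULL, uncorrected = NULL,
                keep_intermediates = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }

  sino_n <- peak_normalize(denormalize(sino))
  peak <- sino_n$peak_norm
  tick("normalize")

  if (is.null(uncorrected))
    uncorrected <- sart(sino_n, n_iter = n_iter, relax = relax)
  tick("uncorrected_recon")

  # transmitted-intensity threshold -> cutoff on normalized attenuation
  t_eff <- -log(threshold) / peak
  if (t_eff >= 1) {
    warning("threshold segments nothing: peak attenuation below -log(threshold)")
    seed <- new_metal_mask(matrix(1, nrow(sino_n$values), ncol(sino_n$values)),
                           "seed")
  } else {
    seed <- global_threshold_mask(sino_n, t_eff)
  }
  mask <- if (mode == "proposed") adaptive_expand(sino_n, seed, W = W, a = a)
          else seed
  tick("segmentation")

  inpainted <- inpaint_linear(sino_n, mask)
  I_sf <- streak_free_image(inpainted, n_iter = n_iter, relax = relax)
  tick("streak_free")

  if (is.null(image_threshold))
    image_threshold <- otsu_threshold(uncorrected$values)
  img_mask <- image_metal_mask(uncorrected, image_threshold)
  I_mf <- metal_free_image(uncorrected, img_mask)
  nd <- normalize_difference(I_sf, I_mf)
  w <- weight_map(nd$D_n, p = p, c = c)
  I_p <- fuse_prior(I_mf, I_sf, w)
  tick("prior")

  P_prior <- prior_sinogram(I_p, sino_n)
  corrected <- replace_metal_trace(sino_n, P_prior, mask)
  tick("projection_correction")

  final <- finalize_image(corrected, img_mask, uncorrected,
                          n_iter = n_iter, relax = relax)
  tick("final_recon")

  out <- list(final = final, uncorrected = uncorrected,
              config = list(mode = mode, threshold = threshold, W = W, a = a,
                            p = p, c = c, n_iter = n_iter, relax = relax,
                            image_threshold = image_threshold,
                            attenuation_cutoff = -log(threshold)),
              timings = timings)
  if (keep_intermediates)
    out$intermediates <- list(seed = seed, mask = mask, inpainted = inpainted,
                              streak_free = I_sf, metal_free = I_mf,
                              weight = w, prior = I_p,
                              prior_sinogram = P_prior, corrected = corrected,
                              image_mask = img_mask)
  class(out) <- "mar"
  out
}

#' Artifact-free reference image
#'
#' The ground-truth comparison image for evaluation: the phantom with metal
#' replaced by its surrounding tissue is projected monochromatically and
#' projected with the same polychromatic model and reconstructed with the
#' same algorithm and settings as the corrected images. Using the identical
#' spectrum and reconstruction keeps the tissue rendering (mild cupping,
#' iteration characteristics) common to reference and corrected images, so
#' their comparison isolates the metal artifacts themselves.
#'
#' @param phantom a \code{ct_phantom}.
#' @param geometry a \code{ct_geometry}.
#' @param spectrum the \code{energy_spectrum} of the simulated scan.
#' @param n_iter,relax SART settings (match the pipeline's).
#' @return a \code{recon_image}.
#' @export
reference_image <- function(phantom, geometry, spectrum = default_spectrum(),
                            n_iter = 20L, relax = 0.25) {
  clean <- phantom
  clean$labels[phantom_metal(phantom)] <-
    .material_ids[[phantom$metal_replacement]]
  sino <- polychromatic_project(clean, geometry, spectrum)
  sart(sino, n_iter = n_iter, relax = relax)
}

#' @export
print.mar <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("mar: %s mode, threshold %g (attenuation cutoff %.3f), W=%d, a=%g, p=%g, c=%g\n",
              cfg$mode, cfg$threshold, cfg$attenuation_cutoff, cfg$W, cfg$a,
              cfg$p, cfg$c))
  cat(sprintf("  SART: %d iterations, relaxation %g\n", cfg$n_iter, cfg$relax))
  if (!is.null(x$intermediates)) {
    n_seed <- sum(mask_values(x$intermediates$seed) == 0)
    n_mask <- sum(mask_values(x$intermediates$mask) == 0)
    cat(sprintf("  metal trace: %d seed pixels, %d after refinement\n",
                n_seed, n_mask))
  }
  cat(sprintf("  total runtime: %.1f s\n", sum(x$timings)))
  invisible(x)
}

#' @export
summary.mar <- function(object, reference = NULL, rois = NULL, ...) {
  out <- list(config = object$config, timings = object$timings)
  if (!is.null(reference) && !is.null(rois)) {
    out$ssim <- vapply(rois, function(r) {
      c(corrected = ssim_roi(object$final, reference, r),
        uncorrected = ssim_roi(object$uncorrected, reference, r))
    }, numeric(2))
  }
  class(out) <- "summary.mar"
  out
}

#' @export
print.summary.mar <- function(x, ...) {
  cat(sprintf("mar run (%s mode, threshold %g)\n", x$config$mode,
              x$config$threshold))
  cat("stage timings (s):\n")
  print(round(x$timings, 2))
  if (!is.null(x$ssim)) {
    cat("SSIM against reference:\n")
    print(round(x$ssim, 4))
  }
  invisible(x)
}

#' @export
plot.mar <- function(x, which = c("uncorrected", "final"), zlim = NULL, ...) {
  imgs <- list(uncorrected = x$uncorrected$values, final = x$final$values)
  if (!is.null(x$intermediates)) {
    imgs$prior <- x$intermediates$prior$values
    imgs$streak_free <- x$intermediates$streak_free$values
  }
  which <- intersect(which, names(imgs))
  if (is.null(zlim)) zlim <- range(unlist(lapply(imgs[which], range)))
  op <- par(mfrow = c(1, length(which)), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (nm in which) {
    z <- imgs[[nm]]
    image(t(z)[, nrow(z):1], col = gray(seq(0, 1, length.out = 256)),
          zlim = zlim, axes = FALSE, main = nm, asp = 1)
  }
  invisible(x)
}
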