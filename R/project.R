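# Forward model: line integrals, polychromatic projection, normalization ------

new_sinogram <- function(values, geometry, pixel_size_mm, peak_norm = NULL,
                         n_saturated = 0L) {
  structure(list(values = values, geometry = geometry,
                 pixel_size_mm = pixel_size_mm, peak_norm = peak_norm,
                 n_saturated = n_saturated),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d detectors x %d views, max %.4g%s\n",
              nrow(x$values), ncol(x$values), max(x$values),
              if (is.null(x$peak_norm)) ""
              else sprintf(" (peak-normalized, peak %.4g)", x$peak_norm)))
  if (x$n_saturated > 0L)
    cat(sprintf("  %d saturated (photon-starved) rays\n", x$n_saturated))
  invisible(x)
}

#' Per-material intersection lengths of projection rays
#'
#' Computes, for each ray of one view, the interpolated intersection length
#' (in cm) with each material of the phantom, using the same Joseph-style ray
#' model as all projection routines.
#'
#' @param phantom a \code{ct_phantom}.
#' @param geometry a \code{ct_geometry} whose \code{nx} matches the phantom.
#' @param view view index (1-based).
#' @param materials material names (default: all materials in the phantom,
#'   including air).
#' @return matrix of path lengths in cm, \code{n_det} rows, one column per
#'   material.
#' @export
path_lengths <- function(phantom, geometry, view = 1L,
                         materials = phantom_materials(phantom)) {
  geom_check(geometry)
  if (nrow(phantom$labels) != geometry$nx)
    stop("phantom size does not match geometry")
  ids <- .material_ids[materials]
  L <- cpp_path_lengths_view(phantom$labels, as.integer(ids),
                             geometry$angles[view], geometry$n_det,
                             geometry$det_spacing,
                             geometry$mode == "fan", geometry$sod)
  colnames(L) <- materials
  L * phantom$pixel_size_mm / 10
}

#' Polychromatic projection of a phantom
#'
#' Simulates attenuation projection data with energy-dependent attenuation:
#' \deqn{P(s,\theta) = -\ln \sum_E w(E) \exp(-\sum_m \mu_m(E) L_m(s,\theta))}
#' Transmitted intensity is clamped at a relative floor to model photon
#' starvation; clamped rays are counted in the result's \code{n_saturated}.
#'
#' @param phantom a \code{ct_phantom}.
#' @param tab a \code{material_table} covering all phantom labels; defaults
#'   to the standard table on the spectrum's energy grid.
#' @param spectrum an \code{energy_spectrum} (default \code{default_spectrum()}).
#' @param geometry a \code{ct_geometry}.
#' @param intensity_floor relative transmitted-intensity floor (default
#'   \code{1e-12}; the floor exists to keep the log finite, not to model a
#'   detector dynamic range).
#' @return an unnormalized \code{sinogram} of attenuation line integrals.
#' @export
polychromatic_project <- function(phantom, geometry,
                                  spectrum = default_spectrum(),
                                  tab = material_table(spectrum$energies),
                                  intensity_floor = 1e-12) {
  geom_check(geometry)
  mats <- phantom_materials(phantom)
  missing <- setdiff(mats, tab$table$name)
  if (length(missing))
    stop("phantom labels not in material table: ", paste(missing, collapse = ", "))
  mu <- tab$mu[mats, , drop = FALSE]
  if (!isTRUE(all.equal(tab$energies, spectrum$energies)))
    mu <- do.call(rbind, lapply(mats, function(m)
      mu_of(tab, m, spectrum$energies)))
  P <- matrix(0, geometry$n_det, geometry$n_views)
  cm_per_px <- phantom$pixel_size_mm / 10
  ids <- as.integer(.material_ids[mats])
  n_sat <- 0L
  for (v in seq_len(geometry$n_views)) {
    L <- cpp_path_lengths_view(phantom$labels, ids, geometry$angles[v],
                               geometry$n_det, geometry$det_spacing,
                               geometry$mode == "fan", geometry$sod) * cm_per_px
    # transmitted fraction per ray: sum_E w(E) exp(-(L %*% mu[,E]))
    att <- L %*% mu                      # n_det x n_energy
    trans <- exp(-att) %*% spectrum$weights
    sat <- trans < intensity_floor
    n_sat <- n_sat + sum(sat)
    trans[sat] <- intensity_floor
    P[, v] <- -log(trans)
  }
  new_sinogram(P, geometry, phantom$pixel_size_mm, n_saturated = n_sat)
}

#' Poisson counting noise for projection data
#'
#' Optional noise stage, off by default in every simulation path: draws
#' Poisson-distributed detector counts around the noiseless transmitted
#' intensity and returns the re-logged attenuation data. Rays whose drawn
#' count is zero are clamped to one count (photon starvation).
#'
#' @param sino an unnormalized \code{sinogram} of attenuation values.
#' @param n_photons incident photons per detector bin.
#' @param seed integer seed making the draw reproducible.
#' @return the noisy \code{sinogram}; \code{n_saturated} counts zero-count
#'   rays.
#' @export
add_poisson_noise <- function(sino, n_photons = 1e6, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"))
  if (!is.null(sino$peak_norm))
    stop("apply noise before peak normalization")
  if (n_photons <= 0) stop("n_photons must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- matrix(stats::rpois(length(sino$values),
                                n_photons * exp(-sino$values)),
                   nrow(sino$values), ncol(sino$values))
  sat <- counts == 0L
  counts[sat] <- 1L
  sino$values <- -log(counts / n_photons)
  sino$n_saturated <- sino$n_saturated + sum(sat)
  sino
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Monochromatic forward projection of an attenuation image
#'
#' Line integrals (in units of the image values times cm) of a pixel image,
#' using the same ray model as \code{\link{path_lengths}}, so that
#' simulate--reconstruct--reproject chains are self-consistent. Linear in the
#' image.
#'
#' @param image numeric matrix of attenuation values (1/cm).
#' @param geometry a \code{ct_geometry}.
#' @param pixel_size_mm pixel size in mm.
#' @return an unnormalized \code{sinogram}.
#' @export
forward_project <- function(image, geometry, pixel_size_mm) {
  geom_check(geometry)
  if (nrow(image) != geometry$nx || ncol(image) != geometry$nx)
    stop("image dimensions do not match geometry")
  P <- cpp_forward_project(image, geometry$angles, geometry$n_det,
                           geometry$det_spacing, geometry$mode == "fan",
                           geometry$sod) * pixel_size_mm / 10
  new_sinogram(P, geometry, pixel_size_mm)
}

#' Peak normalization of projection data
#'
#' Divides the projection data by its global maximum over all views so the
#' maximum is 1, storing the divisor in \code{peak_norm}.
#'
#' @param sino a \code{sinogram}.
#' @return the normalized \code{sinogram}.
#' @export
peak_normalize <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  pk <- max(sino$values)
  if (pk <= 0) stop("cannot peak-normalize an all-zero sinogram")
  prior <- if (is.null(sino$peak_norm)) 1 else sino$peak_norm
  sino$values <- sino$values / pk
  sino$peak_norm <- pk * prior
  sino
}

#' Undo peak normalization
#'
#' @param sino a peak-normalized \code{sinogram}.
#' @return the \code{sinogram} on its original scale.
#' @export
denormalize <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  if (is.null(sino$peak_norm)) return(sino)
  sino$values <- sino$values * sino$peak_norm
  sino$peak_norm <- NULL
  sino
}
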