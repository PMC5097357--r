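#' @useDynLib dmar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx sd
#' @importFrom graphics hist image lines par
#' @importFrom grDevices gray
NULL

# Mass attenuation coefficients (cm^2/g) at anchor energies (keV), compiled
# from standard published photon cross-section tables for the diagnostic
# range, and nominal densities (g/cm^3).  Enamel and dentin are modelled as
# mineralized tissues between cortical bone and soft tissue in composition;
# their coefficients are approximate compilations, adequate for simulation.
.mu_anchor_energies <- c(20, 30, 40, 50, 60, 80, 100, 150)

.mu_over_rho <- list(
  air        = c(0.0008, 0.0004, 0.0003, 0.0002, 0.0002, 0.0002, 0.0002, 0.0001),
  muscle     = c(0.8205, 0.3783, 0.2685, 0.2262, 0.2048, 0.1823, 0.1693, 0.1492),
  soft_tissue= c(0.8040, 0.3710, 0.2640, 0.2230, 0.2020, 0.1800, 0.1670, 0.1470),
  dentin     = c(2.9000, 1.0000, 0.5200, 0.3500, 0.2700, 0.2000, 0.1750, 0.1460),
  bone       = c(4.0010, 1.3310, 0.6655, 0.4242, 0.3148, 0.2229, 0.1855, 0.1480),
  enamel     = c(4.8000, 1.6000, 0.7800, 0.4800, 0.3300, 0.2050, 0.1700, 0.1400),
  titanium   = c(4.0000, 1.2130, 0.5663, 0.3168, 0.2214, 0.1404, 0.1081, 0.0819)
)

.densities <- c(air = 0.0012, muscle = 1.05, soft_tissue = 1.06,
                dentin = 2.14, bone = 1.92, enamel = 2.89, titanium = 4.506)

.material_ids <- c(air = 0L, muscle = 1L, soft_tissue = 2L, bone = 3L,
                   dentin = 4L, enamel = 5L, titanium = 6L)

#' Material attenuation table
#'
#' Tabulates linear attenuation coefficients (1/cm) of the phantom materials
#' (air, muscle, soft tissue, bone, dentin, enamel, titanium) on a shared
#' energy grid. Values are log-log interpolated from anchor points taken from
#' standard published attenuation compilations.
#'
#' @param energy_grid energies in keV, each within 10--150 keV.
#' @param materials material names to include (default: all).
#' @return a \code{material_table}: data frame with one row per material
#'   (columns \code{material_id}, \code{name}, \code{density},
#'   \code{is_metal}) and an attached \code{mu} matrix (materials x energies,
#'   1/cm) plus the energy grid.
#' @export
material_table <- function(energy_grid, materials = names(.material_ids)) {
  if (any(energy_grid < 10 | energy_grid > 150))
    stop("energy grid must lie within 10-150 keV")
  unknown <- setdiff(materials, names(.material_ids))
  if (length(unknown))
    stop("unknown material name(s): ", paste(unknown, collapse = ", "))
  mu <- matrix(0, length(materials), length(energy_grid),
               dimnames = list(materials, NULL))
  for (m in materials) {
    mor <- .mu_over_rho[[m]]
    # log-log interpolation of mass attenuation, then scale by density
    y <- approx(log(.mu_anchor_energies), log(mor), xout = log(energy_grid),
                rule = 2)$y
    mu[m, ] <- exp(y) * .densities[[m]]
  }
  tab <- data.frame(material_id = .material_ids[materials], name = materials,
                    density = .densities[materials],
                    is_metal = materials == "titanium",
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, mu = mu, energies = as.numeric(energy_grid)),
            class = "material_table")
}

#' Look up linear attenuation coefficients
#'
#' @param tab a \code{material_table}.
#' @param material material name.
#' @param energy energies in keV (defaults to the table grid).
#' @return linear attenuation coefficients in 1/cm.
#' @export
mu_of <- function(tab, material, energy = NULL) {
  if (!material %in% rownames(tab$mu))
    stop("unknown material name: ", material)
  if (is.null(energy)) return(tab$mu[material, ])
  exp(approx(log(tab$energies), log(pmax(tab$mu[material, ], 1e-12)),
             xout = log(energy), rule = 2)$y)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("material_table: %d materials on %d energies (%g-%g keV)\n",
              nrow(x$table), length(x$energies), min(x$energies),
              max(x$energies)))
  print(x$table)
  invisible(x)
}

#' Polychromatic x-ray spectrum
#'
#' A simple filtered bremsstrahlung model: Kramers-type weights
#' \code{(kvp - E)} shaped by aluminium and copper pre-filtration,
#' \code{w(E) proportional to (kvp - E) * exp(-mu_Al(E) t_Al - mu_Cu(E) t_Cu)},
#' discretized on an evenly spaced grid from 20 keV to the tube voltage and
#' normalized to unit total weight. The default is a soft, lightly filtered
#' beam (40 kV, 0.5 mm Al): across this band titanium's attenuation varies
#' strongly with energy, so rays through the implants harden severely and
#' the uncorrected reconstruction shows pronounced streak and shadow
#' artifacts, while tissue-only rays stay nearly monochromatic.
#'
#' @param kvp tube voltage in kV (40--150).
#' @param n_bins number of energy bins (>= 8).
#' @param filtration_mm_al aluminium filtration thickness in mm.
#' @param filtration_mm_cu copper filtration thickness in mm.
#' @return an \code{energy_spectrum}: list with \code{energies} (keV) and
#'   \code{weights} (sum to 1).
#' @export
default_spectrum <- function(kvp = 40, n_bins = 21L,
                             filtration_mm_al = 0.5, filtration_mm_cu = 0) {
  if (kvp < 40 || kvp > 150) stop("kvp must be within 40-150 kV")
  if (n_bins < 8L) stop("need at least 8 energy bins")
  e <- seq(20, kvp, length.out = n_bins + 1L)
  e <- (e[-1] + e[-length(e)]) / 2  # bin centres, strictly below kvp
  mu_al_anchor <- c(9.289, 3.045, 1.535, 0.994, 0.750, 0.545, 0.459, 0.378)
  mu_cu_anchor <- c(302.7, 97.8, 43.6, 23.4, 14.3, 6.84, 4.10, 1.99)
  loge <- log(e)
  mu_al <- exp(approx(log(.mu_anchor_energies), log(mu_al_anchor),
                      xout = loge, rule = 2)$y)
  mu_cu <- exp(approx(log(.mu_anchor_energies), log(mu_cu_anchor),
                      xout = loge, rule = 2)$y)
  w <- (kvp - e) * exp(-mu_al * filtration_mm_al / 10 -
                         mu_cu * filtration_mm_cu / 10)
  w <- w / sum(w)
  structure(list(energies = e, weights = w, kvp = kvp),
            class = "energy_spectrum")
}

#' Scan spectrum of a study phantom
#'
#' The fixed simulation spectrum associated with each built-in phantom:
#' 40 kV with 0.5 mm Al for the bilateral-prostheses phantom, 40 kV with
#' 0.3 mm Al for the dental phantom (a slightly softer beam; the thin
#' soft-tissue head needs less filtration to keep tissue rays in the
#' segmentation regime). These pairings are the package's study conditions;
#' simulation scripts and tests draw them from here.
#'
#' @param phantom a \code{ct_phantom} from \code{\link{bilateral_phantom}}
#'   or \code{\link{dental_phantom}} (or their name string).
#' @return an \code{energy_spectrum}.
#' @export
scan_spectrum <- function(phantom) {
  name <- if (inherits(phantom, "ct_phantom")) phantom$name else phantom
  switch(name,
         bilateral = default_spectrum(40, filtration_mm_al = 0.5,
                                      filtration_mm_cu = 0),
         dental = default_spectrum(40, filtration_mm_al = 0.3,
                                   filtration_mm_cu = 0),
         stop("no study spectrum defined for phantom '", name, "'"))
}

#' Degenerate single-energy spectrum
#'
#' @param energy the single energy in keV.
#' @return an \code{energy_spectrum} with one bin of weight 1.
#' @export
single_bin_spectrum <- function(energy) {
  structure(list(energies = energy, weights = 1.0, kvp = energy),
            class = "energy_spectrum")
}

#' Spectrum-weighted mean energy
#'
#' @param spectrum an \code{energy_spectrum}.
#' @return the weighted mean energy in keV.
#' @export
effective_energy <- function(spectrum) {
  sum(spectrum$energies * spectrum$weights)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("energy_spectrum: %d bins, %g-%g keV, effective %0.1f keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              effective_energy(x)))
  invisible(x)
}
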