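# File interchange: 32-bit float TIFF with structured-text sidecars -----------

sidecar_path <- function(path) paste0(path, ".yml")

write_float_tiff <- function(values, path) {
  vmin <- min(values); vmax <- max(values)
  scaled <- if (vmax > vmin) (values - vmin) / (vmax - vmin)
            else values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  list(vmin = vmin, vmax = vmax)
}

read_float_tiff <- function(path, rng) {
  m <- tiff::readTIFF(path)
  if (rng$vmax > rng$vmin) m * (rng$vmax - rng$vmin) + rng$vmin
  else m + rng$vmin
}

#' Write a reconstructed image to TIFF
#'
#' The image is stored as 32-bit float TIFF (rescaled to [0, 1]) with a YAML
#' sidecar (\code{<path>.yml}) holding the value range and provenance.
#'
#' @param image a \code{recon_image} or matrix.
#' @param path output TIFF path.
#' @export
write_image <- function(image, path) {
  vals <- if (inherits(image, "recon_image")) image$values else image
  prov <- if (inherits(image, "recon_image")) image$provenance else NULL
  rng <- write_float_tiff(vals, path)
  meta <- list(type = "recon_image", vmin = rng$vmin, vmax = rng$vmax)
  if (!is.null(prov))
    meta$provenance <- prov[!vapply(prov, is.numeric, TRUE) |
                              lengths(prov) == 1L]
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a reconstructed image written by \code{\link{write_image}}
#'
#' @param path TIFF path with an accompanying sidecar.
#' @return a \code{recon_image}.
#' @export
read_image <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  vals <- read_float_tiff(path, meta)
  new_recon(vals, c(meta$provenance, list(file = path)))
}

#' Write a sinogram to TIFF
#'
#' Detector bins along rows, views along columns, stored as 32-bit float
#' TIFF with a YAML sidecar recording the geometry, pixel size and
#' normalization constant.
#'
#' @param sino a \code{sinogram}.
#' @param path output TIFF path.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  rng <- write_float_tiff(sino$values, path)
  g <- sino$geometry
  yaml::write_yaml(list(
    type = "sinogram", vmin = rng$vmin, vmax = rng$vmax,
    pixel_size_mm = sino$pixel_size_mm, peak_norm = sino$peak_norm,
    n_saturated = sino$n_saturated,
    geometry = list(nx = g$nx, n_views = g$n_views, n_det = g$n_det,
                    det_spacing = g$det_spacing,
                    angular_range = g$angular_range, mode = g$mode,
                    sod = g$sod)), sidecar_path(path))
  invisible(path)
}

#' Read a sinogram written by \code{\link{write_sinogram}}
#'
#' @param path TIFF path with an accompanying sidecar.
#' @return a \code{sinogram}.
#' @export
read_sinogram <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  gm <- meta$geometry
  g <- ct_geometry(nx = gm$nx, n_views = gm$n_views, n_det = gm$n_det,
                   det_spacing = gm$det_spacing,
                   angular_range = gm$angular_range, mode = gm$mode,
                   sod = gm$sod)
  new_sinogram(read_float_tiff(path, meta), g, meta$pixel_size_mm,
               peak_norm = meta$peak_norm,
               n_saturated = if (is.null(meta$n_saturated)) 0L
                             else meta$n_saturated)
}

#' Write a phantom to TIFF
#'
#' Material labels as 8-bit TIFF plus a YAML sidecar with the pixel size,
#' ROI bounding boxes and material legend.
#'
#' @param phantom a \code{ct_phantom}.
#' @param path output TIFF path.
#' @export
write_phantom <- function(phantom, path) {
  tiff::writeTIFF(phantom$labels / 255, path, bits.per.sample = 8L)
  rois <- lapply(phantom$rois, function(r)
    list(name = r$name, row_range = as.integer(range(r$pixels[, 1])),
         col_range = as.integer(range(r$pixels[, 2]))))
  yaml::write_yaml(list(type = "ct_phantom", name = phantom$name,
                        pixel_size_mm = phantom$pixel_size_mm,
                        metal_replacement = phantom$metal_replacement,
                        materials = as.list(.material_ids), rois = rois),
                   sidecar_path(path))
  invisible(path)
}

#' Write a metal mask to TIFF (8-bit, metal = 0)
#'
#' @param mask a \code{metal_mask}.
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask_values(mask), path, bits.per.sample = 8L)
  yaml::write_yaml(list(type = "metal_mask", stage = mask$stage,
                        convention = "metal=0"), sidecar_path(path))
  invisible(path)
}

#' Read a metal mask written by \code{\link{write_mask}}
#'
#' @param path TIFF path.
#' @return a \code{metal_mask}.
#' @export
read_mask <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  new_metal_mask(round(tiff::readTIFF(path)), meta$stage)
}
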