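#' Acquisition geometry for 2D tomography
#'
#' Describes a 2D parallel-beam (default) or fan-beam scan. All detector
#' quantities are expressed in image pixel units; physical scaling is carried
#' by the phantom's \code{pixel_size_mm} and applied by the projection
#' routines.
#'
#' @param nx image grid size (images are \code{nx} x \code{nx}).
#' @param n_views number of projection views over \code{angular_range}.
#' @param n_det number of detector bins. The default spans the image diagonal
#'   with a small margin (729 bins for a 512 image).
#' @param det_spacing detector bin pitch in pixel units.
#' @param angular_range total scan range in degrees (default 360).
#' @param mode \code{"parallel"} or \code{"fan"}.
#' @param sod source-to-origin distance in pixel units (fan beam only).
#' @return an object of class \code{ct_geometry}.
#' @export
ct_geometry <- function(nx = 512L, n_views = 720L, n_det = NULL,
                        det_spacing = 1, angular_range = 360,
                        mode = c("parallel", "fan"), sod = 3 * nx) {
  mode <- match.arg(mode)
  nx <- as.integer(nx)
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (is.null(n_det)) {
    n_det <- as.integer(ceiling(nx * 1.423))
    if (n_det %% 2L == 0L) n_det <- n_det + 1L
  }
  n_det <- as.integer(n_det)
  if (n_det * det_spacing < nx * sqrt(2) && mode == "parallel") {
    warning("detector array does not span the image diagonal; ",
            "outer structures may be truncated")
  }
  angles <- seq(0, angular_range / 180 * pi, length.out = n_views + 1L)[-(n_views + 1L)]
  structure(list(nx = nx, n_views = n_views, n_det = n_det,
                 det_spacing = det_spacing, angular_range = angular_range,
                 mode = mode, sod = sod, angles = angles),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("ct_geometry: %s beam, %d x %d image, %d detectors (pitch %g px), %d views over %g deg\n",
              x$mode, x$nx, x$nx, x$n_det, x$det_spacing, x$n_views,
              x$angular_range))
  invisible(x)
}

geom_check <- function(geometry) {
  if (!inherits(geometry, "ct_geometry")) stop("expected a ct_geometry object")
  geometry
}
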