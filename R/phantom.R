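# Phantom construction helpers ------------------------------------------------

disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

ellipse_mask <- function(n, cx, cy, a, b) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

annular_sector_mask <- function(n, cx, cy, r_in, r_out, phi1, phi2) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  r2 <- (xs - cx)^2 + (ys - cy)^2
  phi <- atan2(ys - cy, xs - cx)  # y grows downward; phi in (-pi, pi]
  r2 >= r_in^2 & r2 <= r_out^2 & phi >= phi1 & phi <= phi2
}

roi_spec <- function(name, rows, cols, exclude = NULL) {
  px <- expand.grid(row = rows, col = cols)
  if (!is.null(exclude)) {
    keep <- !exclude[cbind(px$row, px$col)]
    px <- px[keep, , drop = FALSE]
  }
  structure(list(name = name, pixels = as.matrix(px)), class = "roi_spec")
}

roi_annulus <- function(name, crow, ccol, half_in, half_out, exclude = NULL) {
  px <- expand.grid(row = (crow - half_out):(crow + half_out),
                    col = (ccol - half_out):(ccol + half_out))
  inner <- abs(px$row - crow) <= half_in & abs(px$col - ccol) <= half_in
  px <- px[!inner, , drop = FALSE]
  if (!is.null(exclude)) {
    keep <- !exclude[cbind(px$row, px$col)]
    px <- px[keep, , drop = FALSE]
  }
  structure(list(name = name, pixels = as.matrix(px)), class = "roi_spec")
}

new_phantom <- function(labels, pixel_size_mm, name, rois, profile,
                        metal_replacement) {
  structure(list(labels = labels, pixel_size_mm = pixel_size_mm, name = name,
                 rois = rois, profile = profile,
                 metal_replacement = metal_replacement),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  counts <- table(x$labels)
  names(counts) <- names(.material_ids)[match(names(counts), .material_ids)]
  cat(sprintf("ct_phantom '%s': %d x %d, pixel %g mm\n", x$name,
              nrow(x$labels), ncol(x$labels), x$pixel_size_mm))
  print(counts)
  invisible(x)
}

#' Bilateral prostheses phantom
#'
#' A 2D material-label phantom mimicking bilateral metal prostheses: a
#' near-circular elliptical muscle body containing two symmetric bone
#' shells, each enclosing one titanium implant. Evaluation ROIs and a
#' horizontal profile line through both implants are attached: ROI A sits
#' midway between the implants in the streak/shadow zone, ROI B is a square
#' annulus around the left implant with the metal pixels excluded. The
#' physical scale is fixed (the pixel size shrinks as the grid grows), so all
#' grid sizes describe the same object; at the default 512 grid the pixel
#' size is 0.128 mm. The implant diameter (6.7 mm), body size
#' (5.4 x 5.1 cm) and shell thickness are chosen so that, under the default
#' spectrum, metal-trace projection values clearly exceed all tissue values
#' while the bone-shell flanks stay between the two threshold cutoffs of
#' interest, the regime in which a global threshold isolates the metal
#' trace and the threshold choice decides how cleanly.
#'
#' @param size image grid size in pixels (>= 64).
#' @return a \code{ct_phantom} with fields \code{labels} (size x size integer
#'   matrix of material ids), \code{pixel_size_mm}, \code{rois} (list of ROI
#'   A and B), \code{profile} (profile-line spec) and
#'   \code{metal_replacement} (material standing in for metal in the
#'   artifact-free reference).
#' @export
bilateral_phantom <- function(size = 512L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be at least 64 pixels")
  f <- size / 512
  c0 <- (size + 1) / 2
  lab <- matrix(.material_ids[["air"]], size, size)
  set <- function(mask, mat) lab[mask] <<- .material_ids[[mat]]
  set(ellipse_mask(size, c0, c0, 210 * f, 200 * f), "muscle")
  r_ti <- 26 * f
  r_bone <- max(28 * f, r_ti + 2)  # bone shell never fragments on coarse grids
  bx <- c(c0 - 100 * f, c0 + 100 * f)
  for (x in bx) set(disk_mask(size, x, c0, r_bone), "bone")
  for (x in bx) set(disk_mask(size, x, c0, r_ti), "titanium")

  half_a <- max(6, round(20 * f))
  roi_a <- roi_spec("A", round(c0 - half_a):round(c0 + half_a),
                    round(c0 - half_a):round(c0 + half_a))
  ti <- lab == .material_ids[["titanium"]]
  roi_b <- roi_annulus("B", round(c0), round(bx[1]),
                       max(round(58 * f), ceiling(r_bone) + 2L),
                       max(round(68 * f), ceiling(r_bone) + 5L),
                       exclude = ti)
  profile <- list(row = round(c0),
                  cols = seq(round(0.1 * size), round(0.9 * size)))
  new_phantom(lab, pixel_size_mm = 65.536 / size, name = "bilateral",
              rois = list(A = roi_a, B = roi_b), profile = profile,
              metal_replacement = "muscle")
}

#' Dental phantom
#'
#' A 2D material-label phantom of a jaw section: a near-circular soft-tissue
#' head ellipse, an arch of anterior teeth (dentin cores in thin enamel
#' shells) bulging toward the bottom of the image, and two titanium
#' implants, each osseointegrated in a thin bone collar, at the posterior
#' positions of the same arch. Evaluation ROIs (A on the implant row midway
#' between the implants; B a square annulus around the left implant) and a
#' horizontal profile line through both implants are attached. At the
#' default 512 grid the pixel size is 0.12 mm; see
#' \code{\link{bilateral_phantom}} for the scaling convention. The bone
#' collars play the same projection-domain role as the bilateral phantom's
#' shells; the lighter soft-tissue body places the tooth row's combined
#' attenuation safely below both threshold cutoffs.
#'
#' @param size image grid size in pixels (>= 64).
#' @return a \code{ct_phantom}; see \code{\link{bilateral_phantom}}.
#' @export
dental_phantom <- function(size = 512L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be at least 64 pixels")
  f <- size / 512
  c0 <- (size + 1) / 2
  lab <- matrix(.material_ids[["air"]], size, size)
  set <- function(mask, mat) lab[mask] <<- .material_ids[[mat]]
  set(ellipse_mask(size, c0, c0, 205 * f, 195 * f), "soft_tissue")

  # tooth arch on a circle bulging downward; implant slots at +-57 deg
  arc_row <- c0 + 80 * f
  arc_r <- 190 * f
  teeth_deg <- c(-14, -10, -6, -2, 2, 6, 10, 14)
  r_dentin <- max(4 * f, 1)
  r_enamel <- max(5 * f, r_dentin + 1)
  for (phi in teeth_deg * pi / 180) {
    tc <- c0 + arc_r * sin(phi)
    tr <- arc_row - arc_r * cos(phi)
    set(disk_mask(size, tc, tr, r_enamel), "enamel")
    set(disk_mask(size, tc, tr, r_dentin), "dentin")
  }

  # implants in bone collars at the posterior positions of the arch
  r_ti <- 30 * f
  r_collar <- max(32 * f, r_ti + 2)  # same coarse-grid guard as the shells
  phi_i <- 57 * pi / 180
  bx <- c(c0 - arc_r * sin(phi_i), c0 + arc_r * sin(phi_i))
  brow <- arc_row - arc_r * cos(phi_i)
  for (x in bx) set(disk_mask(size, x, brow, r_collar), "bone")
  for (x in bx) set(disk_mask(size, x, brow, r_ti), "titanium")

  crow <- round(brow)
  half_a <- max(6, round(20 * f))
  roi_a <- roi_spec("A", (crow - half_a):(crow + half_a),
                    round(c0 - half_a):round(c0 + half_a))
  ti <- lab == .material_ids[["titanium"]]
  roi_b <- roi_annulus("B", crow, round(bx[1]),
                       max(round(40 * f), ceiling(r_collar) + 2L),
                       max(round(50 * f), ceiling(r_collar) + 5L),
                       exclude = ti)
  profile <- list(row = crow,
                  cols = seq(round(0.1 * size), round(0.9 * size)))
  new_phantom(lab, pixel_size_mm = 61.44 / size, name = "dental",
              rois = list(A = roi_a, B = roi_b), profile = profile,
              metal_replacement = "soft_tissue")
}

#' Linear attenuation image of a phantom at one energy
#'
#' Maps material labels to linear attenuation coefficients (1/cm) at the
#' given energy.
#'
#' @param phantom a \code{ct_phantom}.
#' @param tab a \code{material_table} covering all phantom labels.
#' @param energy energy in keV.
#' @param replace_metal if \code{TRUE}, metal pixels take the attenuation of
#'   the phantom's \code{metal_replacement} material (artifact-free
#'   reference geometry).
#' @return a numeric matrix of attenuation coefficients (1/cm).
#' @export
phantom_mu_image <- function(phantom, tab, energy, replace_metal = FALSE) {
  ids <- tab$table$material_id
  mu_e <- vapply(tab$table$name, function(m) mu_of(tab, m, energy), 1.0)
  lut <- numeric(max(ids) + 1L)
  lut[ids + 1L] <- mu_e
  img <- matrix(lut[phantom$labels + 1L], nrow(phantom$labels))
  if (replace_metal) {
    met <- phantom$labels == .material_ids[["titanium"]]
    img[met] <- mu_of(tab, phantom$metal_replacement, energy)
  }
  img
}

#' Materials present in a phantom
#'
#' @param phantom a \code{ct_phantom}.
#' @return character vector of material names present in the label map.
#' @export
phantom_materials <- function(phantom) {
  ids <- sort(unique(as.vector(phantom$labels)))
  names(.material_ids)[match(ids, .material_ids)]
}

#' Ground-truth metal pixels of a phantom
#'
#' @param phantom a \code{ct_phantom}.
#' @return logical matrix, \code{TRUE} at titanium pixels.
#' @export
phantom_metal <- function(phantom) {
  phantom$labels == .material_ids[["titanium"]]
}

#' Ground-truth metal trace of a phantom
#'
#' The set of sinogram pixels whose rays intersect titanium: the forward
#' projection of the titanium indicator image is positive there.
#'
#' @param phantom a \code{ct_phantom}.
#' @param geometry a \code{ct_geometry}.
#' @return logical matrix congruent with the phantom's sinograms.
#' @export
metal_trace <- function(phantom, geometry) {
  ti <- matrix(0, nrow(phantom$labels), ncol(phantom$labels))
  ti[phantom_metal(phantom)] <- 1
  forward_project(ti, geometry, phantom$pixel_size_mm)$values > 1e-9
}
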