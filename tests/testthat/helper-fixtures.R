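# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a centred homogeneous disk image (mu = 0.3/cm, radius 20 px) with its
# 128-px parallel geometry and noiseless monochromatic sinogram
disk_case <- function() fixture("disk", function() {
  n <- 128L
  img <- matrix(0, n, n)
  cx <- (n + 1) / 2
  r <- 20
  img[(row(img) - cx)^2 + (col(img) - cx)^2 <= r^2] <- 0.3
  g <- ct_geometry(nx = n, n_views = 180L)
  list(img = img, n = n, cx = cx, r = r, mu = 0.3, g = g,
       sino = forward_project(img, g, pixel_size_mm = 1))
})

# reduced-scale bilateral simulation: phantom, geometry, normalized
# polychromatic sinogram, ground-truth metal trace
bilateral_sim <- function() fixture("bilateral_sim", function() {
  ph <- bilateral_phantom(256L)
  g <- ct_geometry(256L, 360L)
  sino <- peak_normalize(polychromatic_project(ph, g, scan_spectrum(ph)))
  list(ph = ph, g = g, sino = sino, trace = metal_trace(ph, g))
})

dental_sim <- function() fixture("dental_sim", function() {
  ph <- dental_phantom(256L)
  g <- ct_geometry(256L, 360L)
  sino <- peak_normalize(polychromatic_project(ph, g, scan_spectrum(ph)))
  list(ph = ph, g = g, sino = sino, trace = metal_trace(ph, g))
})

# full pipeline arms on a reduced-scale simulation (shared by the
# acceptance tests); returns reference, uncorrected and the three arms
pipeline_case <- function(which = c("bilateral", "dental")) {
  which <- match.arg(which)
  fixture(paste0("pipeline_", which), function() {
    sim <- if (which == "bilateral") bilateral_sim() else dental_sim()
    ref <- reference_image(sim$ph, sim$g, scan_spectrum(sim$ph))
    unc <- sart(sim$sino)
    arms <- list(
      fp05 = mar(sim$sino, "fp_mar", threshold = 0.05, uncorrected = unc),
      fp07 = mar(sim$sino, "fp_mar", threshold = 0.07, uncorrected = unc),
      prop05 = mar(sim$sino, "proposed", threshold = 0.05, uncorrected = unc))
    c(sim, list(ref = ref, unc = unc, arms = arms))
  })
}

# flood-fill connected-component labelling (4-connectivity), used as an
# independent oracle for island/component checks
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# independent brute-force evaluation of the expansion criterion: per view,
# scan for islands pixel by pixel, compute stats, and from each island end
# walk outward pixel by pixel (at most W steps) while the values stay inside
# the island's acceptance band
brute_expand <- function(vals, seed, W, a) {
  out <- seed
  for (v in seq_len(ncol(vals))) {
    s <- 1L
    n <- nrow(vals)
    while (s <= n) {
      if (seed[s, v] == 0) {
        e <- s
        while (e < n && seed[e + 1L, v] == 0) e <- e + 1L
        y <- vals[s:e, v]
        sig <- sqrt(mean((y - mean(y))^2))
        lo <- min(y) - a * sig
        hi <- max(y) + a * sig
        for (k in seq_len(W)) {
          if (s - k < 1 || vals[s - k, v] < lo || vals[s - k, v] > hi) break
          out[s - k, v] <- 0
        }
        for (k in seq_len(W)) {
          if (e + k > n || vals[e + k, v] < lo || vals[e + k, v] > hi) break
          out[e + k, v] <- 0
        }
        s <- e + 1L
      } else s <- s + 1L
    }
  }
  out
}

# the full-scale simulation study (512 px, 720 views, study spectra): the
# artifact-free reference, uncorrected SART and the three correction arms.
# Built once and shared by the Table-1 and profile acceptance blocks.
study_case <- function(which = c("bilateral", "dental")) {
  which <- match.arg(which)
  fixture(paste0("study_", which), function() {
    ph <- if (which == "bilateral") bilateral_phantom(512L)
          else dental_phantom(512L)
    g <- ct_geometry(512L, 720L)
    spec <- scan_spectrum(ph)
    sino <- peak_normalize(polychromatic_project(ph, g, spec))
    ref <- reference_image(ph, g, spec)
    unc <- sart(sino)
    arms <- list(
      unc = unc,
      fp05 = mar(sino, "fp_mar", threshold = 0.05, uncorrected = unc,
                 keep_intermediates = FALSE)$final,
      fp07 = mar(sino, "fp_mar", threshold = 0.07, uncorrected = unc,
                 keep_intermediates = FALSE)$final,
      prop = mar(sino, "proposed", threshold = 0.05, uncorrected = unc,
                 keep_intermediates = FALSE)$final)
    list(ph = ph, g = g, sino = sino, ref = ref, arms = arms)
  })
}
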