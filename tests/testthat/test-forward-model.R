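test_that("path lengths recover analytic chords and partition the ray", {
  d <- disk_case()
  # phantom wrapper around the disk: label 1 = muscle inside radius 20
  lab <- matrix(0L, d$n, d$n)
  lab[d$img > 0] <- 1L
  ph <- structure(list(labels = lab, pixel_size_mm = 1, name = "disk",
                       metal_replacement = "muscle"), class = "ct_phantom")
  L <- path_lengths(ph, d$g, view = 1L)
  ic <- (d$g$n_det + 1) / 2
  # central ray chord = 2r (cm = px/10 here at 1 mm pixels)
  expect_equal(unname(L[ic, "muscle"]), 2 * d$r / 10, tolerance = 1 / 10)
  # a ray far outside the disk intersects nothing but air
  expect_equal(unname(L[5, "muscle"]), 0)
  # per-material lengths partition the in-support chord (all-ones image)
  ones <- matrix(1, d$n, d$n)
  chord <- forward_project(ones, d$g, pixel_size_mm = 1)$values[, 1]
  expect_equal(unname(rowSums(L)), unname(chord), tolerance = 1e-8)
})

test_that("polychromatic projection reduces to the line integral for one bin", {
  ph <- bilateral_phantom(128L)
  g <- ct_geometry(128L, n_views = 8L)
  tab <- material_table(c(30, 50, 70))
  mono <- polychromatic_project(ph, g, single_bin_spectrum(50), tab)
  mu <- phantom_mu_image(ph, tab, 50)
  direct <- forward_project(mu, g, ph$pixel_size_mm)
  expect_equal(mono$values, direct$values, tolerance = 1e-10)
  # air-only rays are exactly zero
  expect_equal(mono$values[1, 1], 0, tolerance = 1e-12)
})

test_that("beam hardening: apparent attenuation per length falls with depth", {
  # two-bin closed form on increasing slab thickness
  w <- c(0.5, 0.5); mu <- c(1.0, 0.4)
  t <- seq(0.5, 6, by = 0.5)
  P <- vapply(t, function(ti) -log(sum(w * exp(-mu * ti))), 1.0)
  expect_true(all(diff(P / t) < 0))
  # and on a simulated disk: normalized P over chord decreases toward centre
  d <- disk_case()
  lab <- matrix(0L, d$n, d$n)
  lab[d$img > 0] <- 3L  # bone disk
  ph <- structure(list(labels = lab, pixel_size_mm = 1, name = "disk",
                       metal_replacement = "bone"), class = "ct_phantom")
  sp <- structure(list(energies = c(30, 70), weights = c(0.5, 0.5), kvp = 70),
                  class = "energy_spectrum")
  sino <- polychromatic_project(ph, ct_geometry(128L, 1L), sp,
                                material_table(c(30, 70)))
  chord <- path_lengths(ph, ct_geometry(128L, 1L), 1L)[, "bone"]
  sel <- chord > 0.5
  ratio <- sino$values[sel, 1] / chord[sel]
  expect_gt(cor(chord[sel], ratio), -1)  # defined
  expect_true(all(diff(ratio[order(chord[sel])]) <= 1e-9))
  # effective mu bounded by the spectral extremes
  tabm <- material_table(c(30, 70))
  expect_true(all(ratio <= mu_of(tabm, "bone", 30) + 1e-9))
  expect_true(all(ratio >= mu_of(tabm, "bone", 70) - 1e-9))
})

test_that("projection of the metal sub-image attains the sinogram peak", {
  sim <- bilateral_sim()
  peak_at <- which(sim$sino$values == max(sim$sino$values), arr.ind = TRUE)
  expect_true(sim$trace[peak_at[1, 1], peak_at[1, 2]])
})

test_that("forward projection is linear and traces a point sinusoid", {
  n <- 64L
  g <- ct_geometry(n, n_views = 90L)
  z <- matrix(0, n, n)
  expect_equal(max(abs(forward_project(z, g, 1)$values)), 0)
  img <- matrix(rnorm(n * n)^2, n, n)
  s1 <- forward_project(img, g, 1)
  s3 <- forward_project(3 * img, g, 1)
  expect_equal(s3$values, 3 * s1$values, tolerance = 1e-12)
  # single bright pixel at (20, 44): trace follows x cos + y sin
  pt <- matrix(0, n, n); pt[20, 44] <- 1
  sp <- forward_project(pt, g, 1)$values
  x <- 44 - (n + 1) / 2; y <- 20 - (n + 1) / 2
  s0 <- (g$n_det + 1) / 2
  for (v in seq(1, 90, by = 10)) {
    expected <- (x * cos(g$angles[v]) + y * sin(g$angles[v])) + s0
    expect_lt(abs(which.max(sp[, v]) - expected), 1.5)
  }
})

test_that("peak normalization has unit maximum and exact round trip", {
  d <- disk_case()
  sn <- peak_normalize(d$sino)
  expect_equal(max(sn$values), 1, tolerance = 1e-9)
  expect_equal(sn$peak_norm, max(d$sino$values))
  back <- denormalize(sn)
  expect_equal(back$values, d$sino$values, tolerance = 1e-12)
  expect_null(back$peak_norm)
  # normalizing twice keeps values and accumulates the constant
  sn2 <- peak_normalize(sn)
  expect_equal(sn2$values, sn$values, tolerance = 1e-12)
  expect_equal(sn2$peak_norm, sn$peak_norm)
  zero <- d$sino; zero$values <- zero$values * 0
  expect_error(peak_normalize(zero), "all-zero")
})

test_that("photon starvation clamps transmission at the documented floor", {
  # a thick titanium bar forces the transmitted fraction under the floor
  n <- 64L
  lab <- matrix(0L, n, n)
  lab[20:44, 8:56] <- 6L
  ph <- structure(list(labels = lab, pixel_size_mm = 2, name = "bar",
                       metal_replacement = "bone"), class = "ct_phantom")
  g <- ct_geometry(n, 2L)
  sp <- single_bin_spectrum(30)
  sino <- polychromatic_project(ph, g, sp, material_table(30),
                                intensity_floor = 1e-4)
  expect_gt(sino$n_saturated, 0)
  expect_lte(max(sino$values), -log(1e-4) + 1e-9)
})

test_that("Poisson noise stage is seeded, reproducible, and optional", {
  d <- disk_case()
  n1 <- add_poisson_noise(d$sino, n_photons = 1e5, seed = 7L)
  n2 <- add_poisson_noise(d$sino, n_photons = 1e5, seed = 7L)
  expect_identical(n1$values, n2$values)
  n3 <- add_poisson_noise(d$sino, n_photons = 1e5, seed = 8L)
  expect_false(identical(n1$values, n3$values))
  # the stage does not disturb the caller's random stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(add_poisson_noise(d$sino, 1e5, 7L))
  expect_identical(runif(3), before)
  # noise vanishes as the photon count grows
  err <- function(x) mean(abs(x$values - d$sino$values))
  expect_lt(err(add_poisson_noise(d$sino, 1e8, 1L)),
            err(add_poisson_noise(d$sino, 1e4, 1L)))
  # refuses normalized input
  expect_error(add_poisson_noise(peak_normalize(d$sino), 1e5), "normaliz")
})

test_that("zero-count rays are clamped to one count and flagged", {
  d <- disk_case()
  thick <- d$sino; thick$values <- thick$values + 20  # transmission ~ 2e-9
  noisy <- add_poisson_noise(thick, n_photons = 100, seed = 3L)
  expect_gt(noisy$n_saturated, 0)
  expect_lte(max(noisy$values), log(100) + 1e-9)
})
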