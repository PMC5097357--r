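test_that("linear in-painting forces the analytic ramp across metal runs", {
  vals <- matrix(0, 10, 1)
  vals[3, 1] <- 0; vals[7, 1] <- 1
  vals[4:6, 1] <- 9  # corrupted metal values to be replaced
  sino <- dmar:::new_sinogram(vals, ct_geometry(7L, 1L, n_det = 10L), 1)
  mask <- matrix(1, 10, 1); mask[4:6, 1] <- 0
  out <- inpaint_linear(sino, dmar:::new_metal_mask(mask, "seed"))
  expect_equal(out$values[4:6, 1], c(0.25, 0.5, 0.75))
  # equal flanking values give a constant fill
  vals2 <- matrix(0.7, 10, 1); vals2[4:6, 1] <- 5
  sino$values <- vals2
  out2 <- inpaint_linear(sino, dmar:::new_metal_mask(mask, "seed"))
  expect_equal(out2$values[4:6, 1], rep(0.7, 3))
  # run touching the detector edge: one-sided constant extension
  mask3 <- matrix(1, 10, 1); mask3[1:3, 1] <- 0
  vals3 <- matrix(0.2, 10, 1); vals3[1:3, 1] <- 4; vals3[4, 1] <- 0.9
  sino$values <- vals3
  out3 <- inpaint_linear(sino, dmar:::new_metal_mask(mask3, "seed"))
  expect_equal(out3$values[1:3, 1], rep(0.9, 3))
})

test_that("in-painting leaves non-metal pixels bitwise unchanged", {
  set.seed(5)
  vals <- matrix(runif(400), 40, 10)
  mask <- matrix((runif(400) > 0.2) * 1, 40, 10)
  sino <- dmar:::new_sinogram(vals, ct_geometry(28L, 10L, n_det = 40L), 1)
  out <- inpaint_linear(sino, dmar:::new_metal_mask(mask, "seed"))
  expect_identical(out$values[mask == 1], vals[mask == 1])
  # a mask with no metal is a no-op
  out2 <- inpaint_linear(sino, dmar:::new_metal_mask(mask * 0 + 1, "seed"))
  expect_identical(out2$values, vals)
})

test_that("metal-free image nullifies exactly the masked pixels", {
  img <- matrix(runif(64), 8, 8)
  mask <- dmar:::new_metal_mask(matrix((runif(64) > 0.3) * 1, 8, 8), "seed")
  mf <- metal_free_image(img, mask)
  expect_true(all(mf$values[mask$values == 0] == 0))
  expect_identical(mf$values[mask$values == 1], img[mask$values == 1])
  allpass <- metal_free_image(img, dmar:::new_metal_mask(matrix(1, 8, 8), "seed"))
  expect_identical(allpass$values, img)
})

test_that("difference normalization maps extremes to 0 and 1", {
  a <- matrix(c(1, 2, 3), 1)
  nd <- normalize_difference(a, a * 0)
  expect_equal(as.vector(nd$D_n), c(0, 0.5, 1))
  expect_equal(nd$D_min, 1)
  expect_equal(nd$D_max, 3)
  # degenerate case: constant difference maps to zero
  nd0 <- normalize_difference(a, a)
  expect_true(all(nd0$D_n == 0))
})

test_that("weight map matches the closed form and its limits", {
  expect_equal(weight_map(matrix(0), p = 10, c = 0.1)[1], 1)
  expect_equal(weight_map(matrix(0.1), p = 10, c = 0.1)[1], 0.5)
  expect_equal(weight_map(matrix(0.2), p = 10, c = 0.1)[1], 1 / 1025)
  dn <- matrix(seq(0, 1, length.out = 201), 1)
  w <- weight_map(dn, p = 10, c = 0.1)
  expect_true(all(diff(as.vector(w)) <= 0))        # monotone non-increasing
  expect_true(all(w > 0 & w <= 1))
  # larger p sharpens the transition around c
  w20 <- weight_map(dn, p = 20, c = 0.1)
  expect_true(all(w20[dn < 0.1] >= w[dn < 0.1]))
  expect_true(all(w20[dn > 0.1] <= w[dn > 0.1]))
  expect_error(weight_map(dn, p = -1), "p must")
  expect_error(weight_map(dn, c = 0), "c must")
})

test_that("prior fusion interpolates within the parents' envelope", {
  set.seed(2)
  a <- matrix(runif(100), 10)
  b <- matrix(runif(100), 10)
  expect_equal(fuse_prior(a, b, matrix(1, 10, 10))$values, a)
  expect_equal(fuse_prior(a, b, matrix(0, 10, 10))$values, b)
  expect_equal(fuse_prior(a, b, matrix(0.5, 10, 10))$values, (a + b) / 2)
  w <- matrix(runif(100), 10)
  f <- fuse_prior(a, b, w)$values
  expect_true(all(f >= pmin(a, b) - 1e-12 & f <= pmax(a, b) + 1e-12))
})

test_that("small c pushes the prior toward the streak-free image", {
  set.seed(9)
  I_mf <- matrix(runif(100), 10)
  I_sf <- matrix(runif(100), 10)
  nd <- normalize_difference(I_sf, I_mf)
  w <- weight_map(nd$D_n, p = 10, c = 1e-6)
  f <- fuse_prior(I_mf, I_sf, w)$values
  off <- nd$D_n > 1e-3
  expect_equal(f[off], I_sf[off], tolerance = 1e-6)
})

test_that("streak-free image is the SART reconstruction of in-painted data", {
  d <- disk_case()
  mask <- dmar:::new_metal_mask(matrix(1, nrow(d$sino$values),
                                       ncol(d$sino$values)), "seed")
  isf <- streak_free_image(inpaint_linear(d$sino, mask), n_iter = 4L)
  expect_identical(isf$values, sart(d$sino, n_iter = 4L)$values)
  expect_equal(dim(isf$values), c(d$n, d$n))
})
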