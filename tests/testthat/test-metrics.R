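test_that("SSIM is 1 on identical crops, symmetric, and bounded", {
  set.seed(31)
  img <- matrix(runif(4900), 70)
  roi <- list(rows = 20:50, cols = 25:55)
  expect_equal(ssim_roi(img, img, roi), 1)
  other <- img + matrix(rnorm(4900, sd = 0.1), 70)
  s1 <- ssim_roi(img, other, roi)
  # dynamic range depends on the reference image, so symmetrize it
  rng_fix <- function(x) (x - min(x)) / (max(x) - min(x))
  a <- rng_fix(img); b <- rng_fix(other)
  expect_equal(ssim_roi(a, b, roi), ssim_roi(b, a, roi), tolerance = 1e-12)
  expect_lte(s1, 1)
  expect_lt(s1, 0.999)
})

test_that("SSIM luminance term matches the closed form for constant shift", {
  set.seed(32)
  img <- matrix(runif(4900), 70)
  roi <- list(rows = 21:51, cols = 21:51)
  shift <- 0.3
  L <- max(img) - min(img)
  C1 <- (0.01 * L)^2
  # constant shift leaves contrast/structure terms at 1 in the limit of the
  # Gaussian window; compare with the per-window closed form
  g <- dmar:::gaussian_kernel_1d()
  crop <- img[16:56, 16:56]
  mu1 <- dmar:::conv_valid(crop + shift, g)
  mu2 <- dmar:::conv_valid(crop, g)
  lum <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  expect_equal(ssim_roi(img + shift, img, roi), mean(lum), tolerance = 1e-10)
})

test_that("SSIM rejects ROIs whose pixels all hug the image border", {
  img <- matrix(runif(400), 20)
  expect_error(ssim_roi(img, img, list(rows = 1:4, cols = 1:20)), "window")
  # an interior ROI smaller than the window is fine: windows extend outward
  expect_equal(ssim_roi(img, img, list(rows = 9:11, cols = 9:11)), 1)
})

test_that("line profiles interpolate bilinearly", {
  img <- matrix(2.5, 30, 30)
  p <- line_profile(img, list(row = 10, cols = 5:25))
  expect_equal(p, rep(2.5, 21))
  # gradient image: fractional row samples interpolate linearly
  gimg <- matrix(rep(1:30, 30), 30, 30)
  p2 <- line_profile(gimg, list(row = 10.5, cols = 5:10))
  expect_equal(p2, rep(10.5, 6))
  # profile through a disk has a plateau about as wide as the diameter
  d <- disk_case()
  rec <- fbp(d$sino)
  prof <- line_profile(rec, list(row = d$cx, cols = 1:d$n))
  plateau <- sum(prof > d$mu / 2)
  expect_lt(abs(plateau - 2 * d$r), 3)
  expect_error(line_profile(img, list(row = 40, cols = 1:5)), "outside")
})

test_that("difference images report signed errors and norms", {
  a <- matrix(runif(100), 10)
  d0 <- difference_image(a, a)
  expect_true(all(d0$values == 0))
  expect_equal(d0$l1, 0)
  dc <- difference_image(a + 0.25, a)
  expect_equal(dc$linf, 0.25)
  expect_equal(dc$l1, 0.25)
  # excluded pixels do not contribute to the norms
  b <- a; b[1, 1] <- a[1, 1] + 5
  excl <- matrix(FALSE, 10, 10); excl[1, 1] <- TRUE
  expect_equal(difference_image(b, a, exclude = excl)$linf, 0)
})
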