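test_that("global threshold mask is the elementwise comparison, >= is metal", {
  set.seed(11)
  m <- matrix(runif(600), 30, 20)
  mask <- global_threshold_mask(m, 0.4)
  expect_identical(mask$values, (m < 0.4) * 1)
  expect_equal(sort(unique(as.vector(mask$values))), c(0, 1))
  m[3, 7] <- 0.4  # boundary value is metal
  expect_equal(global_threshold_mask(m, 0.4)$values[3, 7], 0)
  expect_true(all(global_threshold_mask(m * 0 + 0.1, 0.5)$values == 1))
  expect_error(global_threshold_mask(m, 1.2), "strictly")
})

test_that("find_islands returns per-view runs of metal", {
  mask <- matrix(1, 60, 3)
  mask[10:20, 1] <- 0
  mask[40:45, 1] <- 0
  isl <- find_islands(new_metal_mask(mask, "seed"), 1)
  expect_length(isl, 2)
  expect_equal(isl[[1]], list(s1 = 10L, s2 = 20L))
  expect_equal(isl[[2]], list(s1 = 40L, s2 = 45L))
  expect_length(find_islands(new_metal_mask(mask, "seed"), 2), 0)
  # random mask: runs agree with a flood-fill labelling of the column
  set.seed(7)
  rnd <- matrix((runif(300) > 0.3) * 1, 100, 3)
  for (v in 1:3) {
    isl <- find_islands(rnd, v)
    lab <- flood_label(matrix(rnd[, v] == 0, ncol = 1))
    expect_length(isl, max(lab))
    for (i in seq_along(isl))
      expect_equal(which(lab == i), seq(isl[[i]]$s1, isl[[i]]$s2))
  }
})

test_that("island statistics use the population standard deviation", {
  vals <- matrix(0.5, 10, 1)
  st <- island_statistics(vals, list(s1 = 2L, s2 = 6L), 1)
  expect_equal(st, list(sigma = 0, A = 0.5, B = 0.5))
  vals <- matrix(c(0.6, 0.8, 1.0, 0.6, 1.0, 0.8), 6, 1)
  st <- island_statistics(vals, list(s1 = 1L, s2 = 3L), 1)
  expect_equal(st$A, 1.0)
  expect_equal(st$B, 0.6)
  expect_equal(st$sigma, sqrt(2 * 0.2^2 / 3))  # population convention
  # invariant to pixel ordering
  st2 <- island_statistics(vals, list(s1 = 4L, s2 = 6L), 1)
  expect_equal(st, st2)
})

test_that("adaptive expansion: degenerate band accepts exact matches only", {
  vals <- matrix(0.1, 50, 1)
  vals[20:25, 1] <- 0.9          # uniform island
  vals[26:27, 1] <- 0.9          # equal neighbours adjacent to the boundary
  vals[28, 1] <- 0.9 - 1e-6      # just below the collapsed band
  vals[29, 1] <- 0.9             # behind the break: unreachable by the walk
  seed <- new_metal_mask(replace(matrix(1, 50, 1), 20:25, 0), "seed")
  ex <- adaptive_expand(vals, seed, W = 10L, a = 2)
  expect_equal(ex$values[26:27, 1], c(0, 0))  # exact matches marked
  expect_equal(ex$values[28, 1], 1)   # epsilon below: walk stops here
  expect_equal(ex$values[29, 1], 1)   # not contiguous with the island
  expect_s3_class(ex, "metal_mask")
  expect_equal(ex$stage, "expanded")
})

test_that("adaptive expansion equals the brute-force band criterion", {
  set.seed(42)
  for (case in 1:3) {
    n_s <- 80L; n_v <- 6L
    vals <- matrix(runif(n_s * n_v, 0, 0.3), n_s, n_v)
    # trapezoidal metal bumps
    for (v in seq_len(n_v)) {
      c0 <- sample(20:60, 1)
      w <- sample(4:10, 1)
      prof <- pmin(1, pmax(0, (w - abs(seq_len(n_s) - c0)) / 3))
      vals[, v] <- vals[, v] + prof
    }
    seed <- global_threshold_mask(vals, 0.8)
    ex <- adaptive_expand(vals, seed, W = 12L, a = 2, passes = "s")
    expect_identical(ex$values, brute_expand(vals, seed$values, 12L, 2))
  }
})

test_that("expansion is a superset of the seed and local to the window", {
  sim <- bilateral_sim()
  seed <- global_threshold_mask(sim$sino,
                                -log(0.05) / sim$sino$peak_norm)
  ex <- adaptive_expand(sim$sino, seed, W = 30L, a = 2)
  expect_true(all(ex$values <= seed$values))  # metal set grows (metal = 0)
  # locality: pixels farther than W from every island stay untouched
  W <- 30L
  for (v in seq(1, ncol(seed$values), by = 37)) {
    reach <- rep(FALSE, nrow(seed$values))
    for (isl in find_islands(seed, v))
      reach[max(1, isl$s1 - W):min(nrow(seed$values), isl$s2 + W)] <- TRUE
    newly <- ex$values[, v] == 0 & seed$values[, v] == 1
    expect_true(all(!newly[!reach]))
  }
})

test_that("overlap with dense anatomy raises the band, curbing growth", {
  set.seed(3)
  n_s <- 120L
  vals <- matrix(runif(n_s, 0, 0.25), n_s, 1)
  prof <- pmax(0, (12 - abs(seq_len(n_s) - 60)) / 12)
  vals[, 1] <- vals[, 1] + prof
  seed <- global_threshold_mask(vals, 0.7)
  lowcount <- function(v) {
    ex <- adaptive_expand(v, global_threshold_mask(v, 0.7), W = 20L, a = 2)
    newly <- ex$values == 0 & global_threshold_mask(v, 0.7)$values == 1
    sum(newly & v < 0.3)
  }
  base <- lowcount(vals)
  raised <- vals
  raised[seed$values == 0] <- raised[seed$values == 0] + 0.3
  expect_lte(lowcount(raised), base)
})

test_that("image-domain metal mask is binary global thresholding", {
  img <- matrix(runif(100, 0, 2), 10, 10)
  m <- image_metal_mask(img, 1.0)
  expect_identical(m$values, (img < 1) * 1)
  expect_true(all(image_metal_mask(img, max(img) + 1)$values == 1))
  expect_true(all(m$values %in% c(0, 1)))
})

test_that("image mask captures nearly all true metal on a simulation", {
  sim <- bilateral_sim()
  unc <- sart(sim$sino, n_iter = 8L)
  met <- phantom_metal(sim$ph)
  # threshold halfway between tissue and metal reconstruction levels
  thr <- 0.5 * max(unc$values)
  m <- image_metal_mask(unc, thr)
  expect_gte(sum(m$values == 0 & met) / sum(met), 0.95)
})
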