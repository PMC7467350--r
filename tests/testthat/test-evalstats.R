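test_that("dynamic range is volume-wide, not slice-wise", {
  expect_equal(dynamic_range(array(c(0, 0.25, 1, 0.5), c(2, 2, 1))), 1)
  v <- array(0, c(1, 2, 1)); v[1, , 1] <- c(-0.0015, 0.0045)
  expect_equal(dynamic_range(v), 0.006)
  # two slices with different ranges: the volume-wide range differs from both
  two <- array(0, c(4, 4, 2))
  two[, , 1] <- seq(0, 1.5, length.out = 16)
  two[, , 2] <- seq(2, 5, length.out = 16)
  expect_equal(dynamic_range(two), 5)
  expect_false(dynamic_range(two) == diff(range(two[, , 1])))
  expect_false(dynamic_range(two) == diff(range(two[, , 2])))
  expect_error(dynamic_range(array(1, c(3, 3, 2))), "dynamic range")
})

test_that("SSIM map equals a direct windowed-moment oracle and honors its bounds", {
  set.seed(17)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- x + matrix(rnorm(16 * 16, sd = 0.1), 16, 16)
  L <- max(x) - min(x)
  cfg <- ssim_config(L = L)
  m <- ssim_map(x, y, cfg)
  expect_equal(dim(m), c(6, 6))  # valid windows only
  expect_equal(m, oracle_ssim_map(x, y, L = L), tolerance = 1e-12)
  expect_true(all(m >= -1 & m <= 1 + 1e-12))

  expect_true(all(ssim_map(x, x, cfg) == 1))          # self-similarity exactly 1
  near <- ssim_map(x, x + 1e-6, cfg)
  far <- ssim_map(x, x + 0.05, cfg)
  expect_true(all(near < 1) || all(near <= 1))
  expect_gt(mean(near), mean(far))                     # luminance continuity
  expect_lt(mean(far), 1)
  # symmetry at fixed L
  expect_equal(ssim_map(y, x, cfg), m, tolerance = 1e-14)
})

test_that("pairwise moment merging equals flat recomputation and is order-free", {
  expect_identical(merge_stats(empty_stats(), empty_stats())$n, 0L)
  s <- slice_stats(matrix(c(0.1, 0.9, 0.4, 0.6), 2))
  expect_identical(merge_stats(s, empty_stats()), s)
  # two equal-n groups with equal means: M2 adds, mean unchanged
  a <- slice_stats(matrix(c(0.2, 0.8), 1)); b <- slice_stats(matrix(c(0.5, 0.5), 1))
  m <- merge_stats(a, b)
  expect_equal(m$mean, 0.5); expect_equal(m$M2, a$M2 + b$M2)

  set.seed(23)
  slices <- lapply(1:10, function(i) matrix(runif(64 * 64), 64, 64))
  acc <- Reduce(merge_stats, lapply(slices, slice_stats), empty_stats())
  flat <- unlist(slices)
  expect_equal(acc$mean, mean(flat), tolerance = 1e-10)
  expect_equal(stats_variance(acc), mean((flat - mean(flat))^2),
               tolerance = 1e-10)
  # permuting the fold order changes nothing beyond floating tolerance
  acc2 <- Reduce(merge_stats, lapply(slices[sample(10)], slice_stats),
                 empty_stats())
  expect_equal(acc2$mean, acc$mean, tolerance = 1e-10)
  expect_equal(acc2$M2, acc$M2, tolerance = 1e-8)
})

test_that("streaming volume MSSIM matches two-group closed form and self-equality", {
  set.seed(31)
  truth <- array(runif(32 * 32 * 6), c(32, 32, 6))
  st <- mssim_volume(truth, truth)
  expect_identical(st$mean, 1)
  expect_identical(stats_variance(st), 0)

  test <- truth
  test[, , 4:6] <- 0.5  # constant on half the slices
  cfg <- ssim_config(L = dynamic_range(truth))
  st2 <- mssim_volume(truth, test, cfg)
  g1 <- Reduce(merge_stats, lapply(1:3, function(s)
    slice_stats(ssim_map(truth[, , s], test[, , s], cfg))), empty_stats())
  g2 <- Reduce(merge_stats, lapply(4:6, function(s)
    slice_stats(ssim_map(truth[, , s], test[, , s], cfg))), empty_stats())
  expect_gt(st2$mean, min(g1$mean, g2$mean))
  expect_lt(st2$mean, max(g1$mean, g2$mean))
  expect_equal(st2$mean, merge_stats(g1, g2)$mean, tolerance = 1e-12)
})

test_that("region SNR matches a constructed Gaussian fixture", {
  set.seed(41)
  sigma <- 0.2; offset <- 1.7
  v <- array(rnorm(40 * 40 * 8, 0, sigma), c(40, 40, 8))
  v[5:14, 5:14, ] <- v[5:14, 5:14, ] + offset
  sig <- list(rows = 5:14, cols = 5:14)
  bg <- list(rows = 25:34, cols = 25:34)
  expect_equal(snr(v, sig, bg), offset / sigma, tolerance = 0.1)
  expect_equal(snr(v, bg, bg), 0)
  expect_error(snr(v, sig, list(rows = 10:20, cols = 10:20)), "disjoint")
  expect_error(snr(array(c(1, 2, 3, 3), c(2, 2, 1)),
                   list(rows = 1:2, cols = 1), list(rows = 1:2, cols = 2)),
               "zero variance")
})
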