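test_that("bit reset clears exactly the low bits and is idempotent", {
  expect_identical(bitreset_transform(matrix(0:15, 4), 0), matrix(0:15, 4))
  expect_equal(bitreset_transform(matrix(65535L), 4)[1, 1], 65520L)  # 0xFFFF -> 0xFFF0
  set.seed(2)
  f <- matrix(sample(0:65535, 64 * 64, TRUE), 64, 64)
  for (n in c(1L, 5L, 11L, 16L)) {
    g <- bitreset_transform(f, n)
    expect_true(all(g %% 2^n == 0))            # exhaustive residue check
    expect_true(all(g <= f))                   # systematic down-rounding
    expect_identical(bitreset_transform(g, n), g)
  }
})

test_that("round-trip error and achieved factor are monotone in n_bits", {
  ds <- tiny_dataset()
  f <- ds$projections[, , 1:4]
  mse <- fac <- numeric(0)
  for (n in c(0L, 4L, 8L, 12L)) {
    cp <- codec_param("bit_reset", n)
    dec <- tomopress:::.decode_frames(tomopress:::.encode_frames(f, cp), cp,
                                      nrow(f), ncol(f))
    mse <- c(mse, mean((dec - f)^2))
    fac <- c(fac, achieved_factor(f, cp))
  }
  expect_true(all(diff(mse) >= 0))
  expect_true(all(diff(fac) >= 0))
  expect_equal(mse[1], 0)  # n_bits = 0 round trip is bit-lossless
})

test_that("encode/decode preserves shape and content contracts per codec", {
  ds <- tiny_dataset()
  f <- ds$projections[, , 1]
  cb <- codec_param("bit_reset", 3L)
  dec <- codec_decode(codec_encode(f, cb), cb, nrow(f), ncol(f))
  expect_identical(dec, bitreset_transform(f, 3L))

  cj_hi <- codec_param("jpeg2000", 2)
  cj_lo <- codec_param("jpeg2000", 30)
  dj_hi <- codec_decode(codec_encode(f, cj_hi), cj_hi, nrow(f), ncol(f))
  dj_lo <- codec_decode(codec_encode(f, cj_lo), cj_lo, nrow(f), ncol(f))
  expect_equal(dim(dj_hi), dim(f))
  expect_true(is.integer(dj_hi))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(dj_hi, f), rmse(dj_lo, f))  # quality monotone in rate

  const <- matrix(1234L, 64, 64)
  expect_lte(max(abs(codec_decode(codec_encode(const, cj_hi), cj_hi,
                                  64, 64) - const)), 1)
  expect_identical(codec_decode(codec_encode(const, cb), cb, 64, 64),
                   bitreset_transform(const, 3L))
})

test_that("the optional JPEG XR adapter signals codec unavailable, never a fallback", {
  f <- matrix(0L, 8, 8)
  expect_error(codec_encode(f, codec_param("jpegxr", 80)),
               class = "tomopress_codec_unavailable")
  expect_error(calibrate("jpegxr", 4, f),
               class = "tomopress_codec_unavailable")
})

test_that("achieved factor reflects content redundancy and the mediant bound", {
  set.seed(4)
  noise <- matrix(sample(0:65535, 96 * 96, TRUE), 96, 96)  # incompressible
  cp <- codec_param("bit_reset", 0L)
  expect_lte(achieved_factor(noise, cp), 1.05)
  zeros <- array(0L, c(96, 96, 2))
  expect_gt(achieved_factor(zeros, cp), 10)
  # factor of a concatenated set lies between the per-frame extremes
  ds <- tiny_dataset()
  fr <- lapply(1:6, function(i) ds$projections[, , i])
  per <- vapply(fr, achieved_factor, numeric(1), codec = cp)
  all6 <- achieved_factor(fr, cp)
  expect_gte(all6, min(per)); expect_lte(all6, max(per))
  expect_error(achieved_factor(array(0L, c(4, 4, 0)), cp), "no frames")
})

test_that("bit-reset calibration equals the exhaustive integer-scan oracle", {
  ds <- tiny_dataset()
  sub <- ds$projections[, , seq(1, 91, by = 12)]
  for (target in c(1, 2, 3.5, 6, 40)) {
    cal <- suppressWarnings(calibrate("bit_reset", target, sub))
    ach <- vapply(0:16, function(n)
      achieved_factor(sub, codec_param("bit_reset", n)), numeric(1))
    ok <- which(ach <= target)
    oracle <- if (length(ok) == 0) 0L else max(ok) - 1L
    expect_identical(cal$parameter, oracle)
    expect_equal(cal$achieved_subset, ach[cal$parameter + 1])
  }
})

test_that("jpeg2000 bisection hits the target factor within tolerance", {
  ds <- tiny_dataset()
  sub <- ds$projections[, , seq(1, 91, by = 12)]
  cal <- calibrate("jpeg2000", 3, sub, tolerance = 0.02)
  expect_lte(abs(cal$achieved_subset - 3) / 3, 0.02)
  ver <- achieved_factor(sub, cal)
  expect_equal(ver, cal$achieved_subset, tolerance = 1e-12)
})

test_that("dataset compression keeps bookkeeping identities and monotone size", {
  ds <- tiny_dataset()
  cd1 <- compress_dataset(ds, "bit_reset", 1)
  expect_equal(cd1$codec$parameter, 0L)
  dec <- decode_dataset(cd1)
  expect_identical(dec$projections, ds$projections)  # byte-lossless archive
  expect_identical(dec$darks, ds$darks)
  expect_identical(dec$flats, ds$flats)
  recount <- sum(vapply(unlist(cd1$payloads, recursive = FALSE), length,
                        numeric(1)))
  expect_equal(cd1$achieved_factor, cd1$original_bytes / recount)
  expect_equal(cd1$original_bytes, dataset_raw_bytes(ds))

  # target 8 sits at the edge of what these small frames can reach, so the
  # calibrator may report best-achievable with a warning; sizes still shrink
  sizes <- suppressWarnings(vapply(c(2, 4, 8), function(tf)
    compress_dataset(ds, "jpeg2000", tf)$compressed_bytes, numeric(1)))
  expect_true(all(diff(sizes) <= 0))
})
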