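test_that("flat-field correction normalizes open beam to unity and darks to the floor", {
  ds <- tiny_dataset()
  # a dataset whose 'projections' are flat frames should normalize to ~1
  ds_flat <- ds
  ds_flat$projections <- ds$flats
  ds_flat$geometry$n_angles <- dim(ds$flats)[3]
  Tf <- flat_field_correct(ds_flat)
  expect_equal(mean(Tf), 1, tolerance = 0.005)
  # a dataset whose 'projections' are dark frames should floor near 0
  ds_dark <- ds
  ds_dark$projections <- ds$darks
  Td <- flat_field_correct(ds_dark)
  expect_lt(mean(Td), 0.005)
  expect_gte(min(Td), 1e-6)
})

test_that("flat-field + neg-log recovers the generator's ideal sinogram on near-noise-free data", {
  spec <- phantom_spec(48, features = list(
    phantom_feature("ellipse", c(0, 0), c(16, 16), mu = 2000)))
  geo <- tomo_geometry(12, 48, 1, pixel_size = 1e-6)
  cfg <- acquisition_config(flux_I0 = 6e4, n_darks = 8, n_flats = 60,
                            dark_mean = 0, dark_sigma = 0, flat_drift = 0,
                            rng_seed = 21)
  ds <- simulate_acquisition(make_phantom(spec), geo, cfg)
  L <- neg_log(flat_field_correct(ds))
  ideal <- aperm(ds$ideal, c(3, 2, 1))
  expect_lt(max(abs(L - ideal)), 0.05)
  expect_lt(mean(abs(L - ideal)), 0.01)
})

test_that("neg_log is the Beer-Lambert inversion and rejects non-positive input", {
  expect_equal(neg_log(array(1, c(2, 2, 1))), array(0, c(2, 2, 1)),
               ignore_attr = TRUE)
  expect_equal(neg_log(array(exp(-1), c(2, 2, 1))), array(1, c(2, 2, 1)),
               ignore_attr = TRUE)
  expect_error(neg_log(array(c(1, 0), c(2, 1, 1))), "positive")
})

test_that("Paganin filter: zero-distance identity, DC gain 1, spectral attenuation", {
  ds <- tiny_dataset()
  Tr <- flat_field_correct(ds)[, , 1:4]
  attr(Tr, "geometry") <- ds$geometry
  mu <- function(o) 4 * pi * o$beta / o$wavelength

  o0 <- recon_options(use_paganin = TRUE, distance = 1e-15)
  ret0 <- paganin_filter(Tr, o0)
  expect_equal(ret0 * mu(o0), -log(Tr), tolerance = 1e-6, ignore_attr = TRUE)

  oc <- recon_options(use_paganin = TRUE)
  const <- array(0.5, c(16, 64, 1))
  retc <- paganin_filter(const, oc, pixel_size = 1e-6)
  expect_equal(retc, array(-log(0.5) / mu(oc), c(16, 64, 1)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # white-noise transmission: high-frequency power shrinks, the more so the
  # larger delta/beta and the larger the distance
  set.seed(8)
  wn <- array(0.5 + 0.05 * rnorm(64 * 64), c(64, 64, 1))
  hf_power <- function(opts) {
    r <- paganin_filter(wn, opts, pixel_size = 1e-6)[, , 1]
    sp <- Mod(fft(r - mean(r)))^2
    sum(sp[17:48, 17:48])  # central block of fft layout = high frequencies
  }
  base <- {
    r <- -log(wn[, , 1]); sp <- Mod(fft(r - mean(r)))^2; sum(sp[17:48, 17:48])
  }
  p1 <- hf_power(recon_options(use_paganin = TRUE, delta = 1.5e-7))
  p2 <- hf_power(recon_options(use_paganin = TRUE, delta = 1.5e-6))
  p3 <- hf_power(recon_options(use_paganin = TRUE, delta = 1.5e-6,
                               distance = 0.3))
  mu1 <- mu(recon_options(use_paganin = TRUE))
  expect_lt(p1 * mu1^2, base)   # attenuated relative to plain neg-log
  expect_lt(p2, p1)             # more so at larger delta/beta
  expect_lt(p3, p2)             # and at larger distance
  expect_error(paganin_filter(Tr, recon_options(use_paganin = TRUE,
                                                delta = 1e-7, beta = 1e-9,
                                                distance = -1)), "positive|> 0")
})

test_that("FBP is zero-preserving, linear, and shift-equivariant", {
  geo <- tomo_geometry(45, 64, 1)
  z <- fbp_reconstruct(matrix(0, 45, 64), geo)
  expect_true(all(z$slices == 0))

  spec <- phantom_spec(64, features = list(
    phantom_feature("ellipse", c(6, -3), c(12, 8), mu = 2)))
  sino <- forward_project(make_phantom(spec), geo)[, , 1]
  r1 <- fbp_reconstruct(sino, geo)$slices[, , 1]
  r2 <- fbp_reconstruct(2 * sino, geo)$slices[, , 1]
  expect_equal(r2, 2 * r1, tolerance = 1e-12)

  # translating the object by one voxel translates the reconstruction: the
  # sinogram of the shifted phantom backprojects to the shifted image
  spec_sh <- phantom_spec(64, features = list(
    phantom_feature("ellipse", c(5, -3), c(12, 8), mu = 2)))
  sino_sh <- forward_project(make_phantom(spec_sh), geo)[, , 1]
  rs <- fbp_reconstruct(sino_sh, geo)$slices[, , 1]
  inner <- 20:45
  expect_equal(rs[inner, inner - 1], r1[inner, inner], tolerance = 0.06)
})

test_that("a noise-free disk phantom reconstructs to its attenuation value", {
  mu <- 1800
  spec <- phantom_spec(128, features = list(
    phantom_feature("ellipse", c(0, 0), c(40, 40), mu = mu)))
  geo <- tomo_geometry(361, 128, 1, pixel_size = 1e-6)
  sino <- forward_project(make_phantom(spec), geo)
  rec <- fbp_reconstruct(sino, geo)$slices[, , 1]
  c0 <- (128 + 1) / 2
  msk <- outer(seq_len(128), seq_len(128),
               function(r, c) (r - c0)^2 + (c - c0)^2 <= (0.8 * 40)^2)
  expect_equal(mean(rec[msk]), mu, tolerance = 0.05)
  expect_true(all(rec[outer(seq_len(128), seq_len(128),
    function(r, c) (r - c0)^2 + (c - c0)^2 > 64^2)] == 0))  # circle mask
})

test_that("the full pipeline is deterministic and commutes with a lossless round trip", {
  ds <- tiny_dataset()
  v1 <- reconstruct_pipeline(ds)
  v2 <- reconstruct_pipeline(ds)
  expect_identical(v1$slices, v2$slices)
  rt <- decode_dataset(compress_dataset(ds, "bit_reset", 1))
  v3 <- reconstruct_pipeline(rt)
  expect_identical(v1$slices, v3$slices)
})

test_that("regime and retrieval contrasts show in reconstruction SNR", {
  # standard vs fast presets, and phase retrieval vs absorption
  std <- simulate_preset("fast", 5)   # fast preset as the noisy regime
  rstd <- reconstruct_pipeline(std)
  rpag <- reconstruct_pipeline(std, recon_options(use_paganin = TRUE))
  rg <- preset_snr_regions("fast")
  expect_gt(snr(rpag, rg$signal, rg$background),
            snr(rstd, rg$signal, rg$background))
})
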