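test_that("zero flux produces frames with dark statistics only", {
  geo <- tomo_geometry(12, 32, 2)
  cfg <- acquisition_config(flux_I0 = 0, n_darks = 4, n_flats = 4,
                            dark_mean = 120, dark_sigma = 8, rng_seed = 3)
  ds <- simulate_acquisition(array(0, c(32, 32, 2)), geo, cfg)
  for (stack in list(ds$darks, ds$flats, ds$projections)) {
    expect_equal(mean(stack), 120, tolerance = 0.01)
    expect_equal(sd(as.numeric(stack)), 8, tolerance = 0.1)
  }
})

test_that("at high flux and zero readout noise the flat-normalized ratio recovers exp(-L)", {
  spec <- phantom_spec(48, features = list(
    phantom_feature("ellipse", c(0, 0), c(16, 16), mu = 2000)))
  geo <- tomo_geometry(8, 48, 1, pixel_size = 1e-6)
  cfg <- acquisition_config(flux_I0 = 6e4, n_darks = 2, n_flats = 40,
                            dark_mean = 0, dark_sigma = 0, flat_drift = 0,
                            rng_seed = 5)
  ds <- simulate_acquisition(make_phantom(spec), geo, cfg)
  ratio <- rowMeans(ds$projections, dims = 2) /
    pmax(rowMeans(ds$flats, dims = 2), 1)
  # averaging over angles: compare against the mean ideal transmission
  ideal <- rowMeans(exp(-aperm(ds$ideal, c(3, 2, 1))), dims = 2)
  expect_lt(max(abs(ratio - ideal) / ideal), 0.01)
})

test_that("a fixed seed reproduces the dataset bit-identically and leaves the caller's RNG alone", {
  vol <- make_phantom(phantom_spec(32, features = list(
    phantom_feature("ellipse", c(0, 0), c(10, 10), mu = 2500))))
  geo <- tomo_geometry(20, 32, 1)
  cfg <- acquisition_config(flux_I0 = 20000, n_darks = 2, n_flats = 3,
                            rng_seed = 31L)
  set.seed(99); before <- runif(3)
  a <- simulate_acquisition(vol, geo, cfg)
  set.seed(99)
  b <- simulate_acquisition(vol, geo, cfg)
  expect_identical(a$projections, b$projections)
  expect_identical(a$darks, b$darks)
  expect_identical(a$flats, b$flats)
  expect_identical(runif(3), before)
})

test_that("all emitted frames are valid 16-bit samples", {
  ds <- tiny_dataset()
  for (stack in list(ds$darks, ds$flats, ds$projections)) {
    expect_true(is.integer(stack))
    expect_gte(min(stack), 0)
    expect_lte(max(stack), 65535)
  }
})

test_that("averaged flats converge to gain * flux * flat_structure + dark_mean", {
  geo <- tomo_geometry(2, 64, 4)
  cfg <- acquisition_config(flux_I0 = 20000, n_darks = 2, n_flats = 64,
                            dark_mean = 100, dark_sigma = 10, gain = 1.5,
                            flat_drift = 0.1, rng_seed = 13)
  ds <- simulate_acquisition(array(0, c(64, 64, 4)), geo, cfg)
  fm <- rowMeans(ds$flats, dims = 2)
  expected <- 1.5 * 20000 * tomopress:::.flat_structure(4, 64, 0.1) + 100
  # per-pixel error should be a few flat-mean standard errors at N = 64
  se <- 1.5 * sqrt(20000 / 64)
  expect_lt(max(abs(fm - expected)), 6 * se)
  expect_lt(mean(abs(fm - expected)), 2 * se)
})

test_that("saturating configurations are rejected with a diagnostic", {
  geo <- tomo_geometry(4, 16, 1)
  cfg <- acquisition_config(flux_I0 = 7e4, n_darks = 1, n_flats = 1)
  expect_error(simulate_acquisition(array(0, c(16, 16, 1)), geo, cfg),
               "overflow")
})

test_that("preset regimes contrast as documented", {
  std <- preset_standard(); fst <- preset_fast()
  expect_gt(std$config$flux_I0 / fst$config$flux_I0, 5)
  expect_lt(fst$geometry$n_angles, std$geometry$n_angles)
  expect_lt(fst$geometry$detector_width, std$geometry$detector_width)
})
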