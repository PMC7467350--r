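#' Detector/beam configuration for a simulated acquisition
#'
#' @param flux_I0 expected photon count per detector pixel with no sample.
#' @param n_darks,n_flats number of dark and flat frames (each >= 1).
#' @param dark_mean,dark_sigma offset and Gaussian readout noise of dark
#'   frames, in detector counts.
#' @param gain photons-to-counts conversion factor.
#' @param bit_depth quantization depth; only 16 is supported.
#' @param flat_drift amplitude of the smooth low-order polynomial structure
#'   multiplying the flat field (fraction, e.g. 0.1 for ~+-10%).
#' @param rng_seed integer seed making the simulated dataset reproducible.
#' @return an `acquisition_config` object.
#' @export
acquisition_config <- function(flux_I0, n_darks = 10L, n_flats = 40L,
                               dark_mean = 100, dark_sigma = 10, gain = 1,
                               bit_depth = 16L, flat_drift = 0.1,
                               rng_seed = 1L) {
  stopifnot(flux_I0 >= 0, n_darks >= 1, n_flats >= 1, dark_sigma >= 0,
            gain > 0, flat_drift >= 0)
  if (bit_depth != 16L) stop("only 16-bit quantization is supported")
  structure(list(flux_I0 = flux_I0, n_darks = as.integer(n_darks),
                 n_flats = as.integer(n_flats), dark_mean = dark_mean,
                 dark_sigma = dark_sigma, gain = gain, bit_depth = 16L,
                 flat_drift = flat_drift, rng_seed = as.integer(rng_seed)),
            class = "acquisition_config")
}

# Smooth low-order polynomial flat-field structure, 1 +- about `amplitude`.
.flat_structure <- function(rows, cols, amplitude) {
  u <- if (cols > 1) seq(-1, 1, length.out = cols) else 0  # detector axis
  v <- if (rows > 1) seq(-1, 1, length.out = rows) else 0  # row axis
  ug <- matrix(u, rows, cols, byrow = TRUE)
  vg <- matrix(v, rows, cols)
  1 + amplitude * (0.5 * vg + 0.3 * (ug^2 - 1 / 3) + 0.2 * ug * vg)
}

.quantize16 <- function(x) {
  # round half to even (base round), clip to the 16-bit range
  v <- round(x)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  storage.mode(v) <- "integer"
  v
}

#' Simulate a tomographic acquisition
#'
#' Projections follow `quantize(gain * Poisson(flux_I0 * flat * exp(-L)) +
#' N(dark_mean, dark_sigma))` where `L` are the ideal line integrals; flats
#' use `L = 0` and darks have zero photon flux. Values are quantized by
#' rounding half to even and clipped to `[0, 65535]`. The whole dataset is
#' reproducible (bit-identical) given `config$rng_seed`.
#'
#' @param volume attenuation volume (see [make_phantom()]).
#' @param geometry a [tomo_geometry()].
#' @param config an [acquisition_config()].
#' @param keep_ideal store the noise-free sinogram stack alongside the data
#'   (used by oracle checks).
#' @return a `projection_dataset`: integer arrays `darks`, `flats`,
#'   `projections` of shape `n_slices x detector_width x n_frames`, plus
#'   `geometry`, `config`, `provenance` and (optionally) `ideal`.
#' @export
simulate_acquisition <- function(volume, geometry, config, keep_ideal = TRUE) {
  stopifnot(inherits(geometry, "tomo_geometry"),
            inherits(config, "acquisition_config"))
  sino <- forward_project(volume, geometry)  # [A, W, S]
  S <- geometry$n_slices; W <- geometry$detector_width; A <- geometry$n_angles
  flat <- .flat_structure(S, W, config$flat_drift)
  expected_flat <- config$gain * config$flux_I0 * flat + config$dark_mean
  if (mean(expected_flat > 65535) > 0.01)
    stop("expected counts overflow 16 bits for more than 1% of pixels; lower flux_I0 or gain")
  npix <- S * W
  ds <- .with_seed(config$rng_seed, {
    darks <- .quantize16(array(rnorm(npix * config$n_darks, config$dark_mean,
                                     config$dark_sigma),
                               dim = c(S, W, config$n_darks)))
    lam_flat <- as.vector(config$flux_I0 * flat)
    flats <- array(rpois(npix * config$n_flats, rep(lam_flat, config$n_flats)),
                   dim = c(S, W, config$n_flats))
    flats <- .quantize16(config$gain * flats +
                           rnorm(npix * config$n_flats, config$dark_mean,
                                 config$dark_sigma))
    trans <- exp(-aperm(sino, c(3, 2, 1)))  # [S, W, A]
    lam <- config$flux_I0 * as.vector(flat) * trans
    proj <- array(rpois(length(lam), as.vector(lam)), dim = c(S, W, A))
    proj <- .quantize16(config$gain * proj +
                          rnorm(npix * A, config$dark_mean, config$dark_sigma))
    list(darks = darks, flats = flats, projections = proj)
  })
  structure(list(darks = ds$darks, flats = ds$flats,
                 projections = ds$projections, geometry = geometry,
                 config = config,
                 provenance = sprintf("synthetic acquisition, seed %d, %d angles x %d x %d",
                                      config$rng_seed, A, S, W),
                 ideal = if (keep_ideal) sino else NULL),
            class = "projection_dataset")
}

#' @export
print.projection_dataset <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("<projection_dataset> %d projections (%d x %d), %d darks, %d flats\n",
              d[3], d[1], d[2], dim(x$darks)[3], dim(x$flats)[3]))
  cat("  ", x$provenance, "\n")
  invisible(x)
}

#' Total raw size of a projection dataset in bytes (2 bytes per sample)
#' @param dataset a `projection_dataset`.
#' @return number of bytes.
#' @export
dataset_raw_bytes <- function(dataset) {
  2 * (length(dataset$darks) + length(dataset$flats) +
         length(dataset$projections))
}

.preset_phantom <- function(grid, n_slices, scale) {
  phantom_spec(
    grid_size = grid, n_slices = n_slices, background_mu = 0,
    features = list(
      phantom_feature("ellipse", c(0, 0), c(110, 110) * scale, mu = 3000),
      phantom_feature("ellipse", c(60, -30) * scale, c(30, 18) * scale,
                      mu = 5200, rotation = 0.5),
      phantom_feature("annulus", c(-45, 40) * scale, 35 * scale, mu = 6400,
                      r_inner = 25 * scale),
      phantom_feature("ellipse", c(30, 60) * scale, c(10, 10) * scale, mu = 3600),
      phantom_feature("ellipse", c(-20, -60) * scale, c(4, 4) * scale, mu = 8000)
    ))
}

#' Preset acquisition regimes
#'
#' Fixed desk-scale parameter sets emulating the two beamline regimes: a
#' "standard" high-quality scan (many projections, high flux) and a "fast"
#' scan (fewer, smaller, noisier projections). The phantom is a circular
#' matrix containing an ellipse, an annulus, a low-contrast disk and a small
#' strongly absorbing particle.
#'
#' @param seed RNG seed stored in the acquisition config.
#' @return list with elements `phantom` ([phantom_spec()]), `geometry`
#'   ([tomo_geometry()]) and `config` ([acquisition_config()]).
#' @export
preset_standard <- function(seed = 1L) {
  list(phantom = .preset_phantom(256L, 64L, 1),
       geometry = tomo_geometry(n_angles = 721L, detector_width = 256L,
                                n_slices = 64L, pixel_size = 1e-6),
       config = acquisition_config(flux_I0 = 30000, n_darks = 10L,
                                   n_flats = 40L, dark_mean = 100,
                                   dark_sigma = 10, flat_drift = 0.1,
                                   rng_seed = seed))
}

#' @rdname preset_standard
#' @export
preset_fast <- function(seed = 1L) {
  list(phantom = .preset_phantom(128L, 32L, 0.5),
       geometry = tomo_geometry(n_angles = 181L, detector_width = 128L,
                                n_slices = 32L, pixel_size = 1e-6),
       config = acquisition_config(flux_I0 = 2500, n_darks = 5L,
                                   n_flats = 20L, dark_mean = 100,
                                   dark_sigma = 20, flat_drift = 0.1,
                                   rng_seed = seed))
}

#' Simulate a full preset dataset
#' @param preset `"standard"` or `"fast"`.
#' @param seed RNG seed.
#' @param keep_ideal see [simulate_acquisition()].
#' @return a `projection_dataset`.
#' @export
simulate_preset <- function(preset = c("standard", "fast"), seed = 1L,
                            keep_ideal = TRUE) {
  preset <- match.arg(preset)
  p <- if (preset == "standard") preset_standard(seed) else preset_fast(seed)
  ds <- simulate_acquisition(make_phantom(p$phantom), p$geometry, p$config,
                             keep_ideal = keep_ideal)
  ds$provenance <- paste0(preset, " preset; ", ds$provenance)
  ds
}

#' Regions used for preset SNR measurements
#'
#' The signal region sits in the uniform matrix near the slice center; the
#' background region lies inside the reconstruction circle but outside the
#' sample.
#'
#' @param preset `"standard"` or `"fast"`.
#' @return list with `signal` and `background`, each `list(rows, cols)`.
#' @export
preset_snr_regions <- function(preset = c("standard", "fast")) {
  preset <- match.arg(preset)
  if (preset == "standard")
    list(signal = list(rows = 119:139, cols = 119:139),
         background = list(rows = 123:133, cols = 243:251))
  else
    list(signal = list(rows = 59:69, cols = 59:69),
         background = list(rows = 61:67, cols = 121:125))
}
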