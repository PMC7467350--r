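#' Reconstruction options
#'
#' @param use_paganin apply single-distance Paganin phase retrieval to the
#'   transmission frames instead of the plain negative logarithm.
#' @param delta,beta refractive index decrement and absorption index of the
#'   (assumed homogeneous) object; only their ratio and `beta` enter the
#'   filter. Defaults correspond to delta/beta = 100 at 20 keV.
#' @param distance propagation (sample-detector) distance in meters.
#' @param wavelength X-ray wavelength in meters (default 6.2e-11, ~20 keV).
#' @param fbp_filter `"ramp"` (pure ramp) or `"cosine"` (ramp with
#'   raised-cosine apodization).
#' @param transmission_floor positive floor applied to transmission values
#'   before taking logarithms.
#' @return a `recon_options` object.
#' @export
recon_options <- function(use_paganin = FALSE, delta = 1.5e-6, beta = 1.5e-8,
                          distance = 0.03, wavelength = 6.2e-11,
                          fbp_filter = c("ramp", "cosine"),
                          transmission_floor = 1e-6) {
  fbp_filter <- match.arg(fbp_filter)
  if (use_paganin) {
    stopifnot(delta > 0, beta > 0, distance > 0, wavelength > 0)
    if (!is.finite(delta / beta)) stop("delta/beta must be finite")
  }
  stopifnot(transmission_floor > 0)
  structure(list(use_paganin = use_paganin, delta = delta, beta = beta,
                 distance = distance, wavelength = wavelength,
                 fbp_filter = fbp_filter,
                 transmission_floor = transmission_floor),
            class = "recon_options")
}

#' Flat-field correction
#'
#' Computes per-pixel transmission `T = (P - mean(darks)) /
#' (mean(flats) - mean(darks))`, floored at `eps` so the subsequent
#' logarithm is defined even where noisy pixels go non-positive.
#'
#' @param dataset a `projection_dataset` with at least one dark and flat.
#' @param eps positive transmission floor.
#' @return numeric array `n_slices x detector_width x n_angles` of
#'   transmission values, with the geometry attached as an attribute.
#'   Warns if more than 0.1% of pixels have flat <= dark; rejects above 10%.
#' @export
flat_field_correct <- function(dataset, eps = 1e-6) {
  stopifnot(inherits(dataset, "projection_dataset"))
  if (dim(dataset$darks)[3] < 1 || dim(dataset$flats)[3] < 1)
    stop("need at least one dark and one flat frame")
  D <- rowMeans(dataset$darks, dims = 2)
  Fm <- rowMeans(dataset$flats, dims = 2)
  denom <- Fm - D
  bad <- mean(denom <= 0)
  if (bad > 0.1) stop(sprintf("flat <= dark at %.1f%% of pixels", 100 * bad))
  if (bad > 0.001)
    warning(sprintf("flat <= dark at %.2f%% of pixels", 100 * bad))
  denom[denom <= 0] <- eps
  Tr <- (dataset$projections - as.vector(D)) / as.vector(denom)
  Tr[Tr < eps] <- eps
  attr(Tr, "geometry") <- dataset$geometry
  Tr
}

#' Negative logarithm of transmission
#'
#' Beer-Lambert inversion: maps transmission to line integrals of the
#' attenuation coefficient. Rejects non-positive input (flooring is the
#' caller's job, see [flat_field_correct()]).
#'
#' @param transmission numeric array of transmission values (> 0).
#' @return `-log(transmission)`, same shape and attributes.
#' @export
neg_log <- function(transmission) {
  if (min(transmission) <= 0) stop("transmission must be strictly positive")
  out <- -log(transmission)
  attr(out, "geometry") <- attr(transmission, "geometry")
  out
}

.fftfreq <- function(n) {
  # cycles per sample, numpy fftfreq layout
  c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
}

#' Single-distance Paganin phase retrieval
#'
#' Applies the homogeneous-object transport-of-intensity filter to each
#' transmission frame: `t = -(1/mu) ln( F^-1[ F(T) / (1 + (R delta / mu)
#' |k|^2) ] )` with `mu = 4 pi beta / lambda` and `k` the angular spatial
#' frequency on the detector. The filter has unit DC gain (a constant frame
#' stays constant) and attenuates high frequencies monotonically in
#' `delta/beta` and in the distance `R`. Frames are mirror-padded to twice
#' their size before the FFT to suppress wrap-around.
#'
#' @param transmission array `n_slices x detector_width x n_angles` from
#'   [flat_field_correct()].
#' @param options a [recon_options()] with `use_paganin = TRUE` parameters.
#' @param pixel_size detector pixel pitch in meters; defaults to the
#'   geometry attached to `transmission`.
#' @return array of retrieved thickness-proportional maps (same shape).
#' @export
paganin_filter <- function(transmission, options = recon_options(use_paganin = TRUE),
                           pixel_size = NULL) {
  if (options$delta <= 0 || options$beta <= 0)
    stop("delta and beta must be positive")
  geom <- attr(transmission, "geometry")
  if (is.null(pixel_size)) {
    if (is.null(geom)) stop("pixel_size required when no geometry attribute present")
    pixel_size <- geom$pixel_size
  }
  if (is.matrix(transmission))
    transmission <- array(transmission, dim = c(dim(transmission), 1L))
  d <- dim(transmission)
  S <- d[1]; W <- d[2]; A <- d[3]
  mu <- 4 * pi * options$beta / options$wavelength
  # mirror (reflective) extension to 2x size: even, periodic, no seam
  ridx <- c(seq_len(S), rev(seq_len(S)))
  cidx <- c(seq_len(W), rev(seq_len(W)))
  kr <- 2 * pi * .fftfreq(2 * S) / pixel_size
  kc <- 2 * pi * .fftfreq(2 * W) / pixel_size
  k2 <- outer(kr^2, kc^2, "+")
  H <- 1 / (1 + (options$distance * options$delta / mu) * k2)
  out <- array(0, dim = d)
  floor_t <- options$transmission_floor
  for (a in seq_len(A)) {
    fr <- transmission[, , a][ridx, cidx]
    filt <- Re(fft(fft(fr) * H, inverse = TRUE)) / length(fr)
    filt <- filt[seq_len(S), seq_len(W), drop = FALSE]
    filt[filt < floor_t] <- floor_t
    out[, , a] <- -log(filt) / mu
  }
  attr(out, "geometry") <- geom
  out
}

# frequency response of the discrete ramp filter (Kak & Slaney kernel),
# length p (power of two), optionally apodized by a raised cosine
.ramp_filter_response <- function(p, type = "ramp") {
  f <- numeric(p)
  f[1] <- 0.25
  odd <- seq(1, p / 2, by = 2)
  f[odd + 1] <- -1 / (pi * odd)^2
  f[p + 1 - odd] <- -1 / (pi * odd)^2
  resp <- 2 * Re(fft(f))
  if (type == "cosine") {
    nu <- abs(.fftfreq(p))          # 0 .. 0.5 cycles/sample
    resp <- resp * cos(pi * nu)     # 1 at DC -> 0 at Nyquist
  }
  resp
}

#' Filtered backprojection of a sinogram stack
#'
#' Per-slice parallel-beam FBP: frequency-domain ramp filtering (zero-padded
#' to the next power of two past twice the detector width), linear
#' interpolation in the backprojection, scaling by `pi / (2 n_angles)` and
#' the pixel size so that a disk phantom of attenuation `mu` reconstructs to
#' `mu` in the units the phantom was specified in. Output is masked to the
#' reconstruction circle (zero outside). Linear in the sinogram and fully
#' deterministic.
#'
#' @param sinogram array `n_angles x detector_width x n_slices` (or a single
#'   `n_angles x detector_width` matrix) of line integrals.
#' @param geometry a [tomo_geometry()] with matching dimensions.
#' @param fbp_filter `"ramp"` or `"cosine"`.
#' @param pipeline_tag provenance tag stored on the volume
#'   (`"absorption"` or `"paganin"`).
#' @return a `recon_volume`: list with `slices` (array `g x g x n_slices`,
#'   `g = detector_width`), `voxel_size` and `pipeline_tag`.
#' @export
fbp_reconstruct <- function(sinogram, geometry,
                            fbp_filter = c("ramp", "cosine"),
                            pipeline_tag = "absorption") {
  fbp_filter <- match.arg(fbp_filter)
  stopifnot(inherits(geometry, "tomo_geometry"))
  if (is.matrix(sinogram)) sinogram <- array(sinogram, dim = c(dim(sinogram), 1L))
  d <- dim(sinogram)
  if (d[1] != geometry$n_angles || d[2] != geometry$detector_width)
    stop("sinogram shape does not match geometry")
  W <- d[2]
  p <- 2^ceiling(log2(max(64, 2 * W)))
  resp <- .ramp_filter_response(p, fbp_filter)
  g <- W
  slices <- array(0, dim = c(g, g, d[3]))
  for (s in seq_len(d[3])) {
    sino_da <- t(sinogram[, , s])              # det x angles
    padded <- matrix(0, p, ncol(sino_da))
    padded[seq_len(W), ] <- sino_da
    Fp <- mvfft(padded)
    q <- Re(mvfft(Fp * resp, inverse = TRUE)) / p
    slices[, , s] <- cpp_backproject(q[seq_len(W), , drop = FALSE],
                                     geometry$angles, g, geometry$pixel_size)
  }
  structure(list(slices = slices, voxel_size = geometry$pixel_size,
                 pipeline_tag = pipeline_tag, source = NULL),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<recon_volume> %d x %d x %d (%s), voxel %.3g\n",
              d[1], d[2], d[3], x$pipeline_tag, x$voxel_size))
  invisible(x)
}

#' Full reconstruction pipeline
#'
#' Flat-field correction, then either the negative-logarithm (absorption)
#' branch or Paganin phase retrieval, then filtered backprojection.
#' Deterministic: identical inputs give bit-identical volumes, so the
#' pipeline commutes exactly with any lossless round trip of the dataset.
#'
#' @param dataset a `projection_dataset` (possibly decoded from a
#'   [compress_dataset()] round trip).
#' @param options a [recon_options()].
#' @return a `recon_volume` with `pipeline_tag` `"absorption"` or
#'   `"paganin"`.
#' @export
reconstruct_pipeline <- function(dataset, options = recon_options()) {
  stopifnot(inherits(dataset, "projection_dataset"),
            inherits(options, "recon_options"))
  Tr <- flat_field_correct(dataset, eps = options$transmission_floor)
  pm <- if (options$use_paganin) paganin_filter(Tr, options) else neg_log(Tr)
  sino <- aperm(pm, c(3, 2, 1))  # angles x det x slices
  vol <- fbp_reconstruct(sino, dataset$geometry, options$fbp_filter,
                         pipeline_tag = if (options$use_paganin) "paganin"
                                        else "absorption")
  vol$source <- dataset$provenance
  vol
}
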