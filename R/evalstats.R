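#' SSIM configuration
#'
#' Defaults follow the reference structural-similarity formulation:
#' stabilizers `K1 = 0.01`, `K2 = 0.03`, an 11x11 Gaussian weighting window
#' with sigma 1.5 (normalized to unit sum), unit exponents, and no image
#' downsampling. The dynamic range `L` is taken volume-wide from the ground
#' truth (see [dynamic_range()]); it must be set before computing maps.
#'
#' @param K1,K2 positive dimensionless stabilizers.
#' @param window_size odd window side length in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param L dynamic range of the volume pair under comparison.
#' @param downsample kept for interface completeness; must remain `FALSE`.
#' @return an `ssim_config` object.
#' @export
ssim_config <- function(K1 = 0.01, K2 = 0.03, window_size = 11L, sigma = 1.5,
                        L = NULL, downsample = FALSE) {
  stopifnot(K1 > 0, K2 > 0, window_size >= 3, window_size %% 2 == 1,
            sigma > 0)
  if (!identical(downsample, FALSE))
    stop("downsampling is deliberately not supported")
  structure(list(K1 = K1, K2 = K2, window_size = as.integer(window_size),
                 sigma = sigma, L = L, downsample = FALSE),
            class = "ssim_config")
}

.gauss1d <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)  # 2D window = outer(g, g) sums to 1
}

#' Volume-wide dynamic range
#'
#' The difference between the highest and lowest grey-level value within the
#' full tomographic volume. Used as the SSIM `L` for every slice comparison
#' of that volume pair.
#'
#' @param volume a `recon_volume` or numeric array.
#' @return `max - min` over all voxels; rejects a constant volume.
#' @export
dynamic_range <- function(volume) {
  v <- if (inherits(volume, "recon_volume")) volume$slices else volume
  if (length(v) == 0) stop("empty volume")
  L <- max(v) - min(v)
  if (L == 0) stop("constant volume has zero dynamic range; SSIM undefined")
  L
}

#' Per-pixel SSIM map of two slices
#'
#' Local (Gaussian-weighted) means, variances and covariance enter
#' `SSIM = ((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`. Only windows fully inside the slice
#' are evaluated (no padding), so the map is smaller than the slice by
#' `window_size - 1` in each dimension.
#'
#' @param x,y numeric matrices of identical shape.
#' @param config an [ssim_config()] with `L` set.
#' @return matrix of SSIM values in `[-1, 1]`; identically 1 for `y = x`.
#' @export
ssim_map <- function(x, y, config) {
  stopifnot(inherits(config, "ssim_config"))
  if (!identical(dim(x), dim(y))) stop("slice shapes differ")
  if (is.null(config$L)) stop("config$L must be set (see dynamic_range)")
  g <- .gauss1d(config$window_size, config$sigma)
  C1 <- (config$K1 * config$L)^2
  C2 <- (config$K2 * config$L)^2
  mx <- cpp_sepconv_valid(x, g)
  my <- cpp_sepconv_valid(y, g)
  sxx <- cpp_sepconv_valid(x * x, g) - mx * mx
  syy <- cpp_sepconv_valid(y * y, g) - my * my
  sxy <- cpp_sepconv_valid(x * y, g) - mx * my
  ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx * mx + my * my + C1) * (sxx + syy + C2))
}

#' Streaming moment statistics of SSIM maps
#'
#' `slice_stats` reduces one SSIM map to its pixel count, mean and sum of
#' squared deviations (M2); `merge_stats` combines two such summaries with
#' the pairwise update `delta = mean_b - mean_a; n = n_a + n_b;
#' mean = mean_a + delta n_b / n; M2 = M2_a + M2_b + delta^2 n_a n_b / n`,
#' so a whole volume can be folded slice by slice without ever holding more
#' than one map. The merge is associative and commutative to floating
#' tolerance and an `n = 0` operand is the identity.
#'
#' @param map SSIM map matrix.
#' @param a,b `tomo_stats` objects (or the result of [empty_stats()]).
#' @return a `tomo_stats` object with fields `n`, `mean`, `M2`.
#' @export
slice_stats <- function(map) {
  m <- mean(map)
  structure(list(n = length(map), mean = m, M2 = sum((map - m)^2)),
            class = "tomo_stats")
}

#' @rdname slice_stats
#' @export
empty_stats <- function() {
  structure(list(n = 0L, mean = 0, M2 = 0), class = "tomo_stats")
}

#' @rdname slice_stats
#' @export
merge_stats <- function(a, b) {
  stopifnot(inherits(a, "tomo_stats"), inherits(b, "tomo_stats"))
  if (a$n == 0) return(b)
  if (b$n == 0) return(a)
  n <- a$n + b$n
  delta <- b$mean - a$mean
  structure(list(n = n, mean = a$mean + delta * b$n / n,
                 M2 = a$M2 + b$M2 + delta^2 * a$n * b$n / n),
            class = "tomo_stats")
}

#' Population variance of a moment summary
#' @param stats a `tomo_stats` object.
#' @return `M2 / n` (SSIM maps are treated as full populations of window
#'   positions).
#' @export
stats_variance <- function(stats) {
  if (stats$n == 0) return(NA_real_)
  stats$M2 / stats$n
}

#' @export
print.tomo_stats <- function(x, ...) {
  cat(sprintf("<tomo_stats> n = %d, mean = %.6f, variance = %.3e\n",
              x$n, x$mean, stats_variance(x)))
  invisible(x)
}

#' Layer-wise streaming MSSIM of a volume pair
#'
#' Computes the SSIM map of every slice pair and folds the per-slice moment
#' summaries with [merge_stats()]; never holds more than one map in memory.
#' The dynamic range is taken volume-wide from the ground truth unless `L`
#' is preset in `config`.
#'
#' @param truth,test `recon_volume`s or arrays of identical shape; `truth`
#'   is the reconstruction from uncompressed data.
#' @param config an [ssim_config()].
#' @return a `tomo_stats` with the merged volume statistics; the `L` used is
#'   attached as an attribute.
#' @export
mssim_volume <- function(truth, test, config = ssim_config()) {
  tv <- if (inherits(truth, "recon_volume")) truth$slices else truth
  sv <- if (inherits(test, "recon_volume")) test$slices else test
  if (!identical(dim(tv), dim(sv))) stop("volume shapes differ")
  if (is.matrix(tv)) { tv <- array(tv, c(dim(tv), 1L)); sv <- array(sv, c(dim(sv), 1L)) }
  if (is.null(config$L)) config$L <- dynamic_range(tv)
  acc <- empty_stats()
  for (s in seq_len(dim(tv)[3]))
    acc <- merge_stats(acc, slice_stats(ssim_map(tv[, , s], sv[, , s], config)))
  attr(acc, "L") <- config$L
  acc
}

#' Region-based signal-to-noise ratio of a volume
#'
#' `(mean over signal region - mean over background region) / sd over
#' background region`, pooled over all slices (or the given slice range).
#'
#' @param volume a `recon_volume` or array.
#' @param signal_region,background_region disjoint regions,
#'   `list(rows =, cols =, slices = NULL)` (slices `NULL` means all).
#' @return the SNR; rejects zero background variance.
#' @export
snr <- function(volume, signal_region, background_region) {
  v <- if (inherits(volume, "recon_volume")) volume$slices else volume
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  pick <- function(r) {
    sl <- r$slices %||% seq_len(dim(v)[3])
    v[r$rows, r$cols, sl]
  }
  overlap <- function(a, b) length(intersect(a, b)) > 0
  ssl <- signal_region$slices %||% seq_len(dim(v)[3])
  bsl <- background_region$slices %||% seq_len(dim(v)[3])
  same <- identical(signal_region$rows, background_region$rows) &&
    identical(signal_region$cols, background_region$cols) &&
    identical(ssl, bsl)
  if (!same &&
      overlap(signal_region$rows, background_region$rows) &&
      overlap(signal_region$cols, background_region$cols) &&
      overlap(ssl, bsl))
    stop("signal and background regions must be disjoint")
  sig <- pick(signal_region); bg <- pick(background_region)
  s <- sd(bg)
  if (s == 0) stop("background region has zero variance")
  (mean(sig) - mean(bg)) / s
}
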