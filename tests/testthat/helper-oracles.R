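# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (direct formula evaluation, full-window sums, flat
# recomputation) so they stay independent of the package's streaming /
# separable code paths.

.cache <- new.env(parent = emptyenv())

# small but complete dataset: 64^2 grid, 16 slices, 91 angles
tiny_dataset <- function(seed = 7L) {
  key <- paste0("tiny", seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  spec <- phantom_spec(64, n_slices = 16, background_mu = 0,
    features = list(
      phantom_feature("ellipse", c(0, 0), c(26, 26), mu = 3000),
      phantom_feature("ellipse", c(8, -6), c(8, 5), mu = 5200, rotation = 0.4),
      phantom_feature("annulus", c(-10, 9), 8, mu = 6400, r_inner = 5)))
  geo <- tomo_geometry(91, 64, 16, pixel_size = 1e-6)
  cfg <- acquisition_config(flux_I0 = 30000, n_darks = 4, n_flats = 8,
                            rng_seed = seed)
  .cache[[key]] <- simulate_acquisition(make_phantom(spec), geo, cfg)
  .cache[[key]]
}

# per-voxel membership test for ellipses/annuli, painter's order
oracle_phantom_slice <- function(spec) {
  n <- spec$grid_size
  c0 <- (n - 1) / 2
  sl <- matrix(spec$background_mu, n, n)
  for (row in seq_len(n)) for (col in seq_len(n)) {
    x <- col - 1 - c0; y <- row - 1 - c0
    for (f in spec$features) {
      dx <- x - f$center[1]; dy <- y - f$center[2]
      inside <- if (f$type == "ellipse") {
        u <- cos(f$rotation) * dx + sin(f$rotation) * dy
        v <- -sin(f$rotation) * dx + cos(f$rotation) * dy
        (u / f$axes[1])^2 + (v / f$axes[2])^2 <= 1
      } else {
        r <- sqrt(dx^2 + dy^2)
        r <= f$axes[1] && r >= f$r_inner
      }
      if (inside) sl[row, col] <- f$mu
    }
  }
  sl
}

# direct full-window SSIM evaluation: Gaussian-weighted moments computed by
# explicit sums per window position (no separable trick, no convolution)
oracle_ssim_map <- function(x, y, K1 = 0.01, K2 = 0.03, win = 11L,
                            sigma = 1.5, L) {
  h <- (win - 1) / 2
  g1 <- exp(-(seq(-h, h))^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  nr <- nrow(x) - win + 1; nc <- ncol(x) - win + 1
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    xs <- x[i:(i + win - 1), j:(j + win - 1)]
    ys <- y[i:(i + win - 1), j:(j + win - 1)]
    mx <- sum(w * xs); my <- sum(w * ys)
    vx <- sum(w * xs^2) - mx^2; vy <- sum(w * ys^2) - my^2
    cxy <- sum(w * xs * ys) - mx * my
    out[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  out
}
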