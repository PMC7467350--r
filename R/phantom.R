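#' Describe a geometric phantom feature
#'
#' Features are drawn into the phantom in list order (painter's order: a
#' later feature overwrites earlier ones where they overlap).
#'
#' @param type `"ellipse"` (a disk is an ellipse with equal axes) or
#'   `"annulus"` (circular ring).
#' @param center length-2 numeric, feature center as (x, y) voxel offsets
#'   from the slice center.
#' @param axes length-2 numeric semi-axes in voxels for an ellipse; for an
#'   annulus the first entry is the outer radius.
#' @param mu attenuation coefficient of the feature (inverse length, same
#'   units as the rest of the phantom; must be >= 0).
#' @param rotation in-plane rotation of the ellipse in radians.
#' @param r_inner inner radius (voxels) for an annulus.
#' @param z_range optional length-2 integer range of slices (1-based,
#'   inclusive) the feature occupies; `NULL` means all slices.
#' @return a `phantom_feature` list.
#' @export
phantom_feature <- function(type = c("ellipse", "annulus"), center, axes, mu,
                            rotation = 0, r_inner = NULL, z_range = NULL) {
  type <- match.arg(type)
  stopifnot(length(center) == 2, is.numeric(center),
            length(axes) >= 1, all(axes > 0), is.numeric(mu), length(mu) == 1)
  if (mu < 0) stop("attenuation mu must be >= 0")
  if (length(axes) == 1) axes <- c(axes, axes)
  if (type == "annulus") {
    if (is.null(r_inner)) stop("annulus requires r_inner")
    if (r_inner <= 0 || r_inner >= axes[1]) stop("need 0 < r_inner < outer radius")
    axes <- c(axes[1], axes[1])
  }
  structure(list(type = type, center = as.numeric(center),
                 axes = as.numeric(axes), mu = mu, rotation = rotation,
                 r_inner = r_inner, z_range = z_range),
            class = "phantom_feature")
}

#' Specify a phantom volume
#'
#' @param grid_size voxels per side of each (square) slice.
#' @param n_slices number of slices in the volume.
#' @param features list of [phantom_feature()] objects; drawn in order.
#' @param background_mu attenuation of the background matrix (>= 0).
#' @return a `phantom_spec` object.
#' @details Every feature must lie entirely inside the reconstruction circle
#'   (diameter `grid_size`); a feature whose extent crosses it is rejected.
#' @export
phantom_spec <- function(grid_size, n_slices = 1L, features = list(),
                         background_mu = 0) {
  stopifnot(grid_size >= 8, n_slices >= 1, background_mu >= 0)
  for (f in features) {
    if (!inherits(f, "phantom_feature")) stop("features must be phantom_feature objects")
    extent <- sqrt(sum(f$center^2)) + max(f$axes)
    if (extent > grid_size / 2)
      stop(sprintf("feature extends to radius %.1f, outside the reconstruction circle (radius %.1f)",
                   extent, grid_size / 2))
    if (!is.null(f$z_range)) {
      if (f$z_range[1] < 1 || f$z_range[2] > n_slices || f$z_range[1] > f$z_range[2])
        stop("feature z_range outside 1..n_slices")
    }
  }
  structure(list(grid_size = as.integer(grid_size),
                 n_slices = as.integer(n_slices),
                 features = features, background_mu = background_mu),
            class = "phantom_spec")
}

# Draw the features active on one slice into a grid_size^2 matrix.
.draw_slice <- function(spec, active) {
  n <- spec$grid_size
  c0 <- (n - 1) / 2
  x <- matrix(rep(seq_len(n) - 1 - c0, each = n), n, n)   # col offsets
  y <- matrix(rep(seq_len(n) - 1 - c0, times = n), n, n)  # row offsets
  sl <- matrix(spec$background_mu, n, n)
  for (f in active) {
    dx <- x - f$center[1]
    dy <- y - f$center[2]
    if (f$type == "ellipse") {
      u <- cos(f$rotation) * dx + sin(f$rotation) * dy
      v <- -sin(f$rotation) * dx + cos(f$rotation) * dy
      inside <- (u / f$axes[1])^2 + (v / f$axes[2])^2 <= 1
    } else {
      r <- sqrt(dx^2 + dy^2)
      inside <- r <= f$axes[1] & r >= f$r_inner
    }
    sl[inside] <- f$mu
  }
  sl
}

#' Rasterize a phantom specification into an attenuation volume
#'
#' @param spec a [phantom_spec()].
#' @return numeric array `grid_size x grid_size x n_slices` of attenuation
#'   values (>= 0). Deterministic given `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  zvar <- any(vapply(spec$features, function(f) !is.null(f$z_range), logical(1)))
  n <- spec$grid_size
  vol <- array(0, dim = c(n, n, spec$n_slices))
  if (!zvar) {
    sl <- .draw_slice(spec, spec$features)
    for (s in seq_len(spec$n_slices)) vol[, , s] <- sl
  } else {
    for (s in seq_len(spec$n_slices)) {
      active <- Filter(function(f) is.null(f$z_range) ||
                         (s >= f$z_range[1] && s <= f$z_range[2]),
                       spec$features)
      vol[, , s] <- .draw_slice(spec, active)
    }
  }
  vol
}
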