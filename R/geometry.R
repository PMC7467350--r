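#' Parallel-beam acquisition geometry
#'
#' @param n_angles number of projection angles.
#' @param detector_width detector pixels per row; must cover the
#'   reconstruction circle of the object.
#' @param n_slices detector rows (= slices of the volume).
#' @param pixel_size detector pixel pitch (length units; defaults to 1 um).
#' @param angles optional explicit view angles in radians; default is
#'   equispaced over `[0, pi)`. Must be strictly increasing within `[0, pi)`.
#' @return a `tomo_geometry` object.
#' @export
tomo_geometry <- function(n_angles, detector_width, n_slices,
                          pixel_size = 1e-6, angles = NULL) {
  stopifnot(n_angles >= 1, detector_width >= 2, n_slices >= 1, pixel_size > 0)
  if (is.null(angles)) {
    angles <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  } else {
    if (length(angles) != n_angles) stop("length(angles) != n_angles")
    if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
    if (any(angles < 0 | angles >= pi)) stop("angles must lie in [0, pi)")
  }
  structure(list(n_angles = as.integer(n_angles),
                 detector_width = as.integer(detector_width),
                 n_slices = as.integer(n_slices),
                 pixel_size = pixel_size, angles = angles),
            class = "tomo_geometry")
}

#' Forward-project a volume into ideal sinograms
#'
#' Discrete Radon transform by ray-driven integration with bilinear
#' interpolation. Slice centers sit at `(grid_size - 1) / 2`; angle 0
#' projects along the first in-plane axis, and the detector coordinate of a
#' point at offset (x, y) from the center is `x cos(theta) + y sin(theta)`.
#'
#' @param volume square-slice array `g x g x n_slices` (a single matrix is
#'   treated as one slice).
#' @param geometry a [tomo_geometry()]; `detector_width` must be at least the
#'   slice grid size so the reconstruction circle is covered.
#' @return array `n_angles x detector_width x n_slices` of line integrals
#'   (attenuation integrated along rays, in `mu * pixel_size` units). Linear
#'   in the input volume.
#' @export
forward_project <- function(volume, geometry) {
  stopifnot(inherits(geometry, "tomo_geometry"))
  if (is.matrix(volume)) volume <- array(volume, dim = c(dim(volume), 1L))
  d <- dim(volume)
  if (d[1] != d[2]) stop("volume slices must be square")
  if (geometry$detector_width < d[1])
    stop("detector_width must cover the object grid")
  if (d[3] != geometry$n_slices)
    stop("volume slice count does not match geometry$n_slices")
  out <- array(0, dim = c(geometry$n_angles, geometry$detector_width, d[3]))
  first <- NULL
  for (s in seq_len(d[3])) {
    sl <- volume[, , s]
    if (s > 1 && identical(sl, volume[, , 1]) && !is.null(first)) {
      out[, , s] <- first
      next
    }
    sg <- cpp_forward_project(sl, geometry$angles, geometry$detector_width,
                              geometry$pixel_size)
    if (s == 1) first <- sg
    out[, , s] <- sg
  }
  out
}
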