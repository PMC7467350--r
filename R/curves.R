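#' Plateau-drop criteria for the safe compression factor
#'
#' A curve point departs from the initial plateau when its MSSIM falls more
#' than `plateau_drop_fraction` (relative) below the plateau mean *and*,
#' concomitantly, its SSIM variance exceeds `variance_rise_ratio` times the
#' plateau's median variance.
#'
#' @param plateau_drop_fraction relative MSSIM drop defining departure.
#' @param variance_rise_ratio variance multiple defining departure.
#' @param min_plateau_points minimum number of points the plateau must hold
#'   for a safe factor to exist.
#' @return a `safe_factor_criteria` object.
#' @export
safe_factor_criteria <- function(plateau_drop_fraction = 0.01,
                                 variance_rise_ratio = 2,
                                 min_plateau_points = 2L) {
  stopifnot(plateau_drop_fraction > 0, variance_rise_ratio > 0,
            min_plateau_points >= 1)
  structure(list(plateau_drop_fraction = plateau_drop_fraction,
                 variance_rise_ratio = variance_rise_ratio,
                 min_plateau_points = as.integer(min_plateau_points)),
            class = "safe_factor_criteria")
}

.make_curve <- function(codec_id, pipeline_tag, points) {
  points <- points[order(points$achieved_factor), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(codec_id = codec_id, pipeline_tag = pipeline_tag,
                 points = points),
            class = "compression_curve")
}

#' @export
print.compression_curve <- function(x, ...) {
  cat(sprintf("<compression_curve> %s / %s\n", x$codec_id, x$pipeline_tag))
  print(x$points, digits = 4)
  invisible(x)
}

# Core sweep: compress once per target, decode once, reconstruct and score
# every requested variant against its own ground truth.
.curve_sweep <- function(dataset, codec_id, targets, variants, truths,
                         ssim = ssim_config(), tolerance = 0.02) {
  rows <- lapply(names(variants), function(v)
    data.frame(target_factor = numeric(0), achieved_factor = numeric(0),
               mssim = numeric(0), ssim_variance = numeric(0)))
  names(rows) <- names(variants)
  for (tf in targets) {
    res <- tryCatch({
      cd <- compress_dataset(dataset, codec_id, tf, tolerance = tolerance)
      dec <- decode_dataset(cd)
      pts <- lapply(names(variants), function(v) {
        vol <- reconstruct_pipeline(dec, variants[[v]])
        st <- mssim_volume(truths[[v]], vol, ssim)
        data.frame(target_factor = tf, achieved_factor = cd$achieved_factor,
                   mssim = st$mean, ssim_variance = stats_variance(st))
      })
      names(pts) <- names(variants)
      pts
    }, error = function(e) {
      warning(sprintf("codec point target %.3g failed: %s", tf,
                      conditionMessage(e)))
      pts <- lapply(names(variants), function(v)
        data.frame(target_factor = tf, achieved_factor = NA_real_,
                   mssim = NA_real_, ssim_variance = NA_real_))
      names(pts) <- names(variants)
      pts
    })
    for (v in names(variants)) rows[[v]] <- rbind(rows[[v]], res[[v]])
  }
  lapply(names(variants), function(v) {
    .make_curve(codec_id, if (variants[[v]]$use_paganin) "paganin"
                          else "absorption", rows[[v]])
  }) |> stats::setNames(names(variants))
}

#' MSSIM-versus-compression-factor curve
#'
#' For each target factor: calibrate and compress the dataset, decode,
#' reconstruct, and score the volume against the ground-truth reconstruction
#' from the uncompressed dataset with [mssim_volume()]. A failed codec point
#' is recorded as a missing row (with a warning), never silently dropped.
#'
#' @param dataset a `projection_dataset`.
#' @param codec_id `"bit_reset"` or `"jpeg2000"`.
#' @param targets vector of target compression factors.
#' @param recon_options a [recon_options()] shared by ground truth and test
#'   reconstructions (default: absorption pipeline).
#' @param ssim an [ssim_config()].
#' @param truth optional precomputed ground-truth `recon_volume`.
#' @return a `compression_curve` with points sorted by achieved factor.
#' @export
compression_curve <- function(dataset, codec_id, targets,
                              recon_options = NULL,
                              ssim = ssim_config(), truth = NULL) {
  stopifnot(length(targets) >= 1)
  opts <- recon_options %||% tomopress::recon_options()
  if (is.null(truth)) truth <- reconstruct_pipeline(dataset, opts)
  .curve_sweep(dataset, codec_id, targets,
               variants = list(v = opts),
               truths = list(v = truth), ssim = ssim)$v
}

#' Detect the safe compression factor of a curve
#'
#' Degradation is the joint event the criterion describes: a drop of the
#' MSSIM away from the plateau *and* a concomitant rise of the SSIM
#' variance. The plateau is the leading run of points: starting from the
#' first point, each next point joins the plateau unless its MSSIM falls
#' more than `plateau_drop_fraction` (relative) below the plateau mean MSSIM
#' *and* its SSIM variance exceeds `variance_rise_ratio` times the plateau
#' median variance. The safe factor is the achieved factor of the last
#' plateau point. If fewer than `min_plateau_points` points qualify the
#' first point is already degraded and a `tomopress_no_safe_factor` error is
#' signalled.
#'
#' @param curve a `compression_curve`.
#' @param criteria a [safe_factor_criteria()].
#' @return the safe compression factor (numeric scalar).
#' @export
detect_safe_factor <- function(curve, criteria = safe_factor_criteria()) {
  stopifnot(inherits(curve, "compression_curve"),
            inherits(criteria, "safe_factor_criteria"))
  pts <- curve$points[stats::complete.cases(curve$points), , drop = FALSE]
  if (nrow(pts) < criteria$min_plateau_points + 1)
    stop("need at least min_plateau_points + 1 curve points")
  keep <- 1L
  for (k in 2:nrow(pts)) {
    pl_mssim <- mean(pts$mssim[seq_len(keep)])
    pl_var <- median(pts$ssim_variance[seq_len(keep)])
    dropped <- pts$mssim[k] < (1 - criteria$plateau_drop_fraction) * pl_mssim
    risen <- pts$ssim_variance[k] > criteria$variance_rise_ratio * pl_var
    if (dropped && risen) break
    keep <- k
  }
  if (keep < criteria$min_plateau_points)
    .stopf("no safe factor: the first curve point is already degraded",
           class = "tomopress_no_safe_factor")
  pts$achieved_factor[keep]
}
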