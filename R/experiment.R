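#' Experiment configuration
#'
#' Bundles everything a full compression-impact experiment needs: the
#' acquisition regime, the codecs and target factors to sweep, the
#' reconstruction variants, SSIM settings and safe-factor criteria. The
#' default target sweep spans the factors flanking the safe regions
#' (plateau and drop) so the detector has both to find.
#'
#' @param preset `"standard"` or `"fast"` (see [preset_standard()]); or pass
#'   `phantom`, `geometry`, `config` explicitly.
#' @param codecs character vector of codec ids (>= 1).
#' @param target_factors numeric vector of target compression factors (>= 2
#'   values).
#' @param variants subset of `c("absorption", "paganin")`.
#' @param ssim an [ssim_config()].
#' @param criteria a [safe_factor_criteria()].
#' @param paganin a [recon_options()] used for the paganin variant.
#' @param output_dir optional directory for the JSON/CSV/figure report.
#' @param seed RNG seed recorded in all outputs.
#' @param phantom,geometry,config explicit study definition overriding
#'   `preset`.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(preset = "standard",
                              codecs = c("bit_reset", "jpeg2000"),
                              target_factors = c(1.5, 2, 3, 4, 5, 6, 8, 10, 12),
                              variants = c("absorption", "paganin"),
                              ssim = ssim_config(),
                              criteria = safe_factor_criteria(),
                              paganin = recon_options(use_paganin = TRUE),
                              output_dir = NULL, seed = 1L,
                              phantom = NULL, geometry = NULL, config = NULL) {
  if (length(codecs) < 1) stop("need at least one codec")
  if (length(target_factors) < 2) stop("need at least two target factors")
  if (!all(codecs %in% c("bit_reset", "jpeg2000", "jpegxr")))
    stop("unknown codec id")
  variants <- match.arg(variants, c("absorption", "paganin"),
                        several.ok = TRUE)
  if (is.null(phantom) != is.null(geometry) ||
      is.null(geometry) != is.null(config))
    stop("phantom, geometry and config must be given together")
  if (is.null(phantom)) preset <- match.arg(preset, c("standard", "fast"))
  structure(list(preset = preset, codecs = codecs,
                 target_factors = sort(target_factors), variants = variants,
                 ssim = ssim, criteria = criteria, paganin = paganin,
                 output_dir = output_dir, seed = as.integer(seed),
                 phantom = phantom, geometry = geometry, config = config),
            class = "experiment_config")
}

# flatten a config into plain lists for the JSON report echo
.config_echo <- function(cfg) {
  list(preset = if (is.null(cfg$phantom)) cfg$preset else "explicit",
       codecs = cfg$codecs, target_factors = cfg$target_factors,
       variants = cfg$variants, seed = cfg$seed,
       ssim = cfg$ssim[c("K1", "K2", "window_size", "sigma")],
       criteria = unclass(cfg$criteria),
       paganin = cfg$paganin[c("delta", "beta", "distance", "wavelength")])
}

#' Run a full compression-impact experiment
#'
#' Simulates (or builds from the explicit spec) the dataset, reconstructs
#' the per-variant ground truths from uncompressed data, sweeps every codec
#' over the target factors (compressing once per target and scoring every
#' variant), detects safe factors, and optionally writes a JSON report, a
#' CSV of all curve points and MSSIM-vs-factor figures. Deterministic given
#' the seed: a rerun reproduces the curves byte-identically.
#'
#' @param config an [experiment_config()].
#' @return (invisibly) the report: a list with `seed`, `config`, `curves`
#'   (per codec/variant data frames), `safe_factors`, `achieved_factors`,
#'   `original_bytes` and `snr` of the ground-truth volumes.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(config$phantom)) {
    dataset <- simulate_preset(config$preset, config$seed)
    regions <- preset_snr_regions(config$preset)
  } else {
    cfg <- config$config; cfg$rng_seed <- config$seed
    dataset <- simulate_acquisition(make_phantom(config$phantom),
                                    config$geometry, cfg)
    regions <- NULL
  }
  variants <- list()
  if ("absorption" %in% config$variants)
    variants$absorption <- recon_options(use_paganin = FALSE)
  if ("paganin" %in% config$variants)
    variants$paganin <- config$paganin
  truths <- lapply(variants, function(v) reconstruct_pipeline(dataset, v))
  curves <- list()
  safe_factors <- list()
  achieved <- list()
  for (cid in config$codecs) {
    sw <- .curve_sweep(dataset, cid, config$target_factors, variants, truths,
                       config$ssim)
    for (v in names(sw)) {
      key <- paste(cid, v, sep = ".")
      curves[[key]] <- sw[[v]]
      safe_factors[[key]] <- tryCatch(detect_safe_factor(sw[[v]],
                                                         config$criteria),
                                      error = function(e) NA_real_)
      achieved[[key]] <- sw[[v]]$points$achieved_factor
    }
  }
  snrs <- if (!is.null(regions))
    lapply(truths, function(tv) snr(tv, regions$signal, regions$background))
  else NULL
  report <- list(package = "tomopress",
                 version = as.character(utils::packageVersion("tomopress")),
                 seed = config$seed, config = .config_echo(config),
                 original_bytes = dataset_raw_bytes(dataset),
                 curves = lapply(curves, function(cu) cu$points),
                 pipeline_tags = lapply(curves, function(cu) cu$pipeline_tag),
                 safe_factors = safe_factors,
                 achieved_factors = achieved,
                 snr = snrs)
  if (!is.null(config$output_dir))
    .write_report(report, curves, config$output_dir)
  invisible(report)
}

.write_report <- function(report, curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  all_pts <- do.call(rbind, lapply(names(curves), function(k) {
    p <- curves[[k]]$points
    p$codec <- curves[[k]]$codec_id
    p$variant <- curves[[k]]$pipeline_tag
    p
  }))
  utils::write.csv(all_pts, file.path(dir, "curves.csv"), row.names = FALSE)
  for (k in names(curves)) {
    f <- file.path(dir, paste0("curve_", gsub("[^a-z0-9_.]", "_", k), ".png"))
    try(.plot_curve(curves[[k]], f), silent = TRUE)
  }
  invisible(NULL)
}

# MSSIM +- SD over achieved compression factor, one codec/variant
.plot_curve <- function(curve, file) {
  grDevices::png(file, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  p <- curve$points[stats::complete.cases(curve$points), , drop = FALSE]
  s <- sqrt(p$ssim_variance)
  plot(p$achieved_factor, p$mssim, type = "b", pch = 19,
       ylim = range(c(p$mssim - s, p$mssim + s, 1)),
       xlab = "achieved compression factor", ylab = "MSSIM",
       main = sprintf("%s / %s", curve$codec_id, curve$pipeline_tag))
  graphics::arrows(p$achieved_factor, p$mssim - s, p$achieved_factor,
                   p$mssim + s, angle = 90, code = 3, length = 0.04)
  invisible(NULL)
}

#' Line-profile comparison of a truth/test slice pair
#'
#' Extracts a vertical profile (by default along the centered vertical
#' axis) from both slices, optionally rendering a zoomed overlay figure.
#' Posterization shows up as a reduced number of distinct values along the
#' profile of the compressed slice.
#'
#' @param truth_slice,test_slice matrices of identical shape.
#' @param col profile column (1-based); default the centered column.
#' @param zoom side length of the zoom window for the rendered figure.
#' @param file optional PNG path for the overlay figure.
#' @return list with `profile` (data frame `index`, `truth`, `test`, one row
#'   per image row), `max_abs_diff`, and the distinct-value counts of both
#'   profiles.
#' @export
line_profile_report <- function(truth_slice, test_slice, col = NULL,
                                zoom = 100L, file = NULL) {
  if (!identical(dim(truth_slice), dim(test_slice)))
    stop("slice shapes differ")
  nc <- ncol(truth_slice)
  if (is.null(col)) col <- as.integer(ceiling(nc / 2))
  if (col < 1 || col > nc) stop("profile line outside the image")
  prof <- data.frame(index = seq_len(nrow(truth_slice)),
                     truth = truth_slice[, col], test = test_slice[, col])
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
    n <- nrow(prof)
    z0 <- max(1, floor((n - zoom) / 2)); z1 <- min(n, z0 + zoom - 1)
    zz <- prof[z0:z1, ]
    plot(zz$index, zz$truth, type = "l", col = "red", xlab = "row",
         ylab = "value", main = sprintf("line profile, column %d", col))
    graphics::lines(zz$index, zz$test, col = "blue")
    graphics::legend("topright", legend = c("uncompressed", "compressed"),
                     col = c("red", "blue"), lty = 1, bty = "n")
  }
  list(profile = prof,
       max_abs_diff = max(abs(prof$truth - prof$test)),
       distinct_truth = length(unique(prof$truth)),
       distinct_test = length(unique(prof$test)))
}
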