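#' Persist and reload projection datasets
#'
#' A dataset directory holds one 16-bit TIFF per frame
#' (`dark_NNNN.tif`, `flat_NNNN.tif`, `proj_NNNN.tif`) plus a
#' `sidecar.json` with geometry, acquisition config and provenance. The
#' round trip is sample-exact.
#'
#' @param dataset a `projection_dataset`.
#' @param dir target/source directory.
#' @return `write_projection_dataset`: the directory, invisibly;
#'   `read_projection_dataset`: a `projection_dataset` (without the ideal
#'   sinogram).
#' @export
write_projection_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "projection_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wstack <- function(arr, prefix) {
    for (i in seq_len(dim(arr)[3]))
      tiff::writeTIFF(arr[, , i] / 65535,
                      file.path(dir, sprintf("%s_%04d.tif", prefix, i)),
                      bits.per.sample = 16L, compression = "none")
  }
  wstack(dataset$darks, "dark")
  wstack(dataset$flats, "flat")
  wstack(dataset$projections, "proj")
  g <- dataset$geometry
  side <- list(geometry = list(n_angles = g$n_angles,
                               detector_width = g$detector_width,
                               n_slices = g$n_slices,
                               pixel_size = g$pixel_size, angles = g$angles),
               config = unclass(dataset$config),
               provenance = dataset$provenance,
               counts = list(darks = dim(dataset$darks)[3],
                             flats = dim(dataset$flats)[3],
                             projections = dim(dataset$projections)[3]))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_projection_dataset
#' @export
read_projection_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  g <- side$geometry
  geometry <- tomo_geometry(g$n_angles, g$detector_width, g$n_slices,
                            g$pixel_size, angles = g$angles)
  cf <- side$config
  config <- acquisition_config(cf$flux_I0, cf$n_darks, cf$n_flats,
                               cf$dark_mean, cf$dark_sigma, cf$gain,
                               cf$bit_depth, cf$flat_drift, cf$rng_seed)
  rstack <- function(prefix, n) {
    arr <- NULL
    for (i in seq_len(n)) {
      fr <- tiff::readTIFF(file.path(dir, sprintf("%s_%04d.tif", prefix, i)))
      if (is.null(arr)) arr <- array(0L, dim = c(dim(fr), n))
      arr[, , i] <- as.integer(round(fr * 65535))
    }
    arr
  }
  structure(list(darks = rstack("dark", side$counts$darks),
                 flats = rstack("flat", side$counts$flats),
                 projections = rstack("proj", side$counts$projections),
                 geometry = geometry, config = config,
                 provenance = side$provenance, ideal = NULL),
            class = "projection_dataset")
}

#' Persist and reload compressed datasets
#'
#' Payloads are written one file per frame (`.bz2`/`.gz`/`.xz` for the
#' bit-reset path, `.j2k` standard codestreams for JPEG 2000) with a JSON
#' index holding codec identity, parameter, byte totals and geometry.
#'
#' @param cd a `compressed_dataset`.
#' @param dir target/source directory.
#' @return `write_compressed_dataset`: the directory, invisibly;
#'   `read_compressed_dataset`: a `compressed_dataset`.
#' @export
write_compressed_dataset <- function(cd, dir) {
  stopifnot(inherits(cd, "compressed_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (cd$codec$codec_id == "jpeg2000") "j2k"
         else switch(cd$codec$lossless_backend, bzip2 = "bz2", gzip = "gz",
                     xz = "xz")
  for (grp in names(cd$payloads)) {
    pl <- cd$payloads[[grp]]
    for (i in seq_along(pl))
      writeBin(pl[[i]], file.path(dir, sprintf("%s_%04d.%s", grp, i, ext)))
  }
  g <- cd$geometry
  idx <- list(codec = unclass(cd$codec),
              original_bytes = cd$original_bytes,
              compressed_bytes = cd$compressed_bytes,
              achieved_factor = cd$achieved_factor,
              target_factor = cd$target_factor,
              frame_dim = cd$frame_dim, extension = ext,
              counts = lapply(cd$payloads, length),
              geometry = list(n_angles = g$n_angles,
                              detector_width = g$detector_width,
                              n_slices = g$n_slices,
                              pixel_size = g$pixel_size, angles = g$angles),
              config = unclass(cd$config), provenance = cd$provenance)
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_compressed_dataset
#' @export
read_compressed_dataset <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  codec <- codec_param(idx$codec$codec_id, idx$codec$parameter,
                       idx$codec$lossless_backend,
                       target_factor = idx$codec$target_factor,
                       achieved_subset = idx$codec$achieved_subset)
  payloads <- lapply(stats::setNames(nm = names(idx$counts)), function(grp) {
    lapply(seq_len(idx$counts[[grp]]), function(i) {
      f <- file.path(dir, sprintf("%s_%04d.%s", grp, i, idx$extension))
      readBin(f, "raw", file.info(f)$size)
    })
  })
  g <- idx$geometry
  cf <- idx$config
  structure(list(payloads = payloads, codec = codec,
                 original_bytes = idx$original_bytes,
                 compressed_bytes = idx$compressed_bytes,
                 achieved_factor = idx$achieved_factor,
                 target_factor = idx$target_factor,
                 frame_dim = idx$frame_dim,
                 geometry = tomo_geometry(g$n_angles, g$detector_width,
                                          g$n_slices, g$pixel_size,
                                          angles = g$angles),
                 config = acquisition_config(cf$flux_I0, cf$n_darks,
                                             cf$n_flats, cf$dark_mean,
                                             cf$dark_sigma, cf$gain,
                                             cf$bit_depth, cf$flat_drift,
                                             cf$rng_seed),
                 provenance = idx$provenance),
            class = "compressed_dataset")
}

#' Persist and reload reconstructed volumes
#'
#' Slices are written as 16-bit TIFFs normalized to the volume's global
#' range, which is stored in `volume.json` together with voxel size and
#' pipeline tag; reading restores floating-point values (to normalization
#' precision).
#'
#' @param volume a `recon_volume`.
#' @param dir target/source directory.
#' @return `write_recon_volume`: the directory, invisibly;
#'   `read_recon_volume`: a `recon_volume`.
#' @export
write_recon_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "recon_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lo <- min(volume$slices); hi <- max(volume$slices)
  scale <- if (hi > lo) hi - lo else 1
  for (i in seq_len(dim(volume$slices)[3]))
    tiff::writeTIFF((volume$slices[, , i] - lo) / scale,
                    file.path(dir, sprintf("slice_%04d.tif", i)),
                    bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(min = lo, max = hi,
                            n_slices = dim(volume$slices)[3],
                            voxel_size = volume$voxel_size,
                            pipeline_tag = volume$pipeline_tag,
                            source = volume$source),
                       file.path(dir, "volume.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_recon_volume
#' @export
read_recon_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE)
  scale <- if (meta$max > meta$min) meta$max - meta$min else 1
  slices <- NULL
  for (i in seq_len(meta$n_slices)) {
    fr <- tiff::readTIFF(file.path(dir, sprintf("slice_%04d.tif", i)))
    if (is.null(slices)) slices <- array(0, dim = c(dim(fr), meta$n_slices))
    slices[, , i] <- fr * scale + meta$min
  }
  structure(list(slices = slices, voxel_size = meta$voxel_size,
                 pipeline_tag = meta$pipeline_tag,
                 source = meta$source %||% NULL),
            class = "recon_volume")
}
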