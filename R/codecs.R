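#' Codec identity and parameter
#'
#' @param codec_id one of `"bit_reset"`, `"jpeg2000"`, `"jpegxr"`.
#' @param parameter codec-native control: for `bit_reset` the integer number
#'   of least-significant bits to reset (0..16); for `jpeg2000` the
#'   codestream rate (target compression ratio of the encoder); for
#'   `jpegxr` a quality percentage in (0, 100].
#' @param lossless_backend entropy coder applied to the raw sample buffer
#'   after bit reset (`"bzip2"`, `"gzip"` or `"xz"`; default bzip2).
#' @param target_factor,achieved_subset optional calibration bookkeeping
#'   filled in by [calibrate()].
#' @return a `codec_param` object.
#' @export
codec_param <- function(codec_id = c("bit_reset", "jpeg2000", "jpegxr"),
                        parameter, lossless_backend = "bzip2",
                        target_factor = NULL, achieved_subset = NULL) {
  codec_id <- match.arg(codec_id)
  if (codec_id == "bit_reset") {
    if (parameter != as.integer(parameter) || parameter < 0 || parameter > 16)
      stop("bit_reset parameter must be an integer in [0, 16]")
    parameter <- as.integer(parameter)
  }
  if (codec_id == "jpeg2000" && parameter < 1)
    stop("jpeg2000 rate parameter must be >= 1")
  if (codec_id == "jpegxr" && (parameter <= 0 || parameter > 100))
    stop("jpegxr quality must be in (0, 100]")
  if (!lossless_backend %in% c("bzip2", "gzip", "xz"))
    stop("unsupported lossless backend")
  structure(list(codec_id = codec_id, parameter = parameter,
                 lossless_backend = lossless_backend,
                 target_factor = target_factor,
                 achieved_subset = achieved_subset),
            class = "codec_param")
}

#' Reset the least-significant bits of 16-bit samples
#'
#' Sets the `n_bits` lowest bits of every sample to zero, i.e. maps each
#' value to `floor(value / 2^n_bits) * 2^n_bits`. Idempotent; output never
#' exceeds the input (systematic down-rounding).
#'
#' @param frame integer matrix/array with values in `[0, 65535]`.
#' @param n_bits integer in `[0, 16]`.
#' @return frame of the same shape with the low bits cleared.
#' @export
bitreset_transform <- function(frame, n_bits) {
  stopifnot(n_bits == as.integer(n_bits), n_bits >= 0, n_bits <= 16)
  if (n_bits == 0) return(frame)
  d <- dim(frame)
  v <- as.integer(frame)
  mask <- as.integer(65536 - 2^n_bits)  # n_bits = 16 -> mask 0
  out <- bitwAnd(v, mask)
  dim(out) <- d
  out
}

.serialize_u16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2, endian = "little")
}

.deserialize_u16 <- function(r, rows, cols) {
  v <- readBin(r, "integer", n = length(r) / 2, size = 2, signed = FALSE,
               endian = "little")
  matrix(v, nrow = rows, ncol = cols)
}

# normalize frames input (matrix, 3D array, or list of matrices) to 3D array
.as_frame_array <- function(frames) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    arr <- array(0L, dim = c(d, length(frames)))
    for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
    storage.mode(arr) <- "integer"
    return(arr)
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  storage.mode(frames) <- "integer"
  frames
}

# batch encode: 3D array -> list of raw payloads
.encode_frames <- function(frames, codec) {
  frames <- .as_frame_array(frames)
  d <- dim(frames)
  switch(codec$codec_id,
    bit_reset = {
      lapply(seq_len(d[3]), function(i) {
        memCompress(.serialize_u16(bitreset_transform(frames[, , i],
                                                      codec$parameter)),
                    codec$lossless_backend)
      })
    },
    jpeg2000 = .jp2_encode(frames, codec$parameter),
    jpegxr = .stopf("codec unavailable: no JPEG XR backend in this build",
                    class = "tomopress_codec_unavailable"))
}

# batch decode: list of raw payloads -> integer array rows x cols x n
.decode_frames <- function(payloads, codec, rows, cols) {
  switch(codec$codec_id,
    bit_reset = {
      arr <- array(0L, dim = c(rows, cols, length(payloads)))
      for (i in seq_along(payloads)) {
        arr[, , i] <- .deserialize_u16(
          memDecompress(payloads[[i]], codec$lossless_backend), rows, cols)
      }
      arr
    },
    jpeg2000 = .jp2_decode(payloads, rows, cols),
    jpegxr = .stopf("codec unavailable: no JPEG XR backend in this build",
                    class = "tomopress_codec_unavailable"))
}

#' Encode / decode a single frame
#'
#' For `bit_reset`, `codec_decode(codec_encode(f))` reproduces
#' `bitreset_transform(f, n_bits)` exactly (bit-identical at `n_bits = 0`);
#' for `jpeg2000` the round trip is the codec's lossy approximation.
#'
#' @param frame 2D integer matrix in the 16-bit range.
#' @param codec a [codec_param()].
#' @param payload raw vector produced by `codec_encode`.
#' @param rows,cols frame shape for decoding.
#' @return `codec_encode`: raw vector; `codec_decode`: integer matrix.
#' @export
codec_encode <- function(frame, codec) {
  stopifnot(is.matrix(frame))
  .encode_frames(frame, codec)[[1]]
}

#' @rdname codec_encode
#' @export
codec_decode <- function(payload, codec, rows, cols) {
  .decode_frames(list(payload), codec, rows, cols)[, , 1]
}

#' Achieved compression factor of a set of frames
#'
#' Total raw bytes (2 per sample) divided by total encoded bytes.
#'
#' @param frames matrix, `rows x cols x n` array, or list of matrices.
#' @param codec a [codec_param()].
#' @return the achieved compression factor (> 0).
#' @export
achieved_factor <- function(frames, codec) {
  frames <- .as_frame_array(frames)
  if (length(frames) == 0) stop("no frames supplied")
  enc <- .encode_frames(frames, codec)
  (2 * length(frames)) / sum(vapply(enc, length, numeric(1)))
}

#' Calibrate a codec parameter to a target compression factor
#'
#' Finds, by interval bisection on a sample subset, the codec parameter
#' whose achieved compression factor matches `target_factor`. For the
#' integer-parameterized `bit_reset` codec the result is the largest
#' `n_bits` whose achieved factor does not exceed the target (the achieved
#' factor is down-rounded relative to the target); for `jpeg2000` the rate
#' is bisected until the achieved factor is within `tolerance` (relative).
#'
#' @param codec_id `"bit_reset"` or `"jpeg2000"`.
#' @param target_factor requested compression factor (>= 1).
#' @param sample_frames frames to calibrate on (matrix, array or list).
#' @param tolerance relative tolerance on the achieved factor (continuous
#'   parameters only).
#' @param max_iter bisection iteration cap.
#' @return a [codec_param()] with `target_factor` and `achieved_subset` set.
#'   If the target is unreachable within the parameter range, the best
#'   achievable parameter is returned with a warning.
#' @export
calibrate <- function(codec_id, target_factor, sample_frames,
                      tolerance = 0.02, max_iter = 20L) {
  stopifnot(target_factor >= 1)
  frames <- .as_frame_array(sample_frames)
  if (length(frames) == 0) stop("sample_frames must be non-empty")
  if (codec_id == "bit_reset") {
    af <- function(n) achieved_factor(frames, codec_param("bit_reset", n))
    a0 <- af(0L)
    if (a0 > target_factor) {
      # even the lossless path exceeds the target: n_bits = 0 is the
      # minimal-loss parameter satisfying "do not exceed" vacuously
      return(codec_param("bit_reset", 0L, target_factor = target_factor,
                         achieved_subset = a0))
    }
    a16 <- af(16L)
    if (a16 <= target_factor) {
      warning("target factor unreachable for bit_reset; best achievable returned")
      return(codec_param("bit_reset", 16L, target_factor = target_factor,
                         achieved_subset = a16))
    }
    # invariant: af(lo) <= target < af(hi); achieved is monotone in n_bits
    lo <- 0L; a_lo <- a0; hi <- 16L
    while (hi - lo > 1L) {
      mid <- as.integer((lo + hi) %/% 2)
      am <- af(mid)
      if (am <= target_factor) { lo <- mid; a_lo <- am } else hi <- mid
    }
    return(codec_param("bit_reset", lo, target_factor = target_factor,
                       achieved_subset = a_lo))
  }
  if (codec_id == "jpeg2000") {
    af <- function(r) achieved_factor(frames, codec_param("jpeg2000", r))
    lo <- 1; hi <- max(2 * target_factor, 8)
    a_lo <- af(lo); a_hi <- af(hi)
    grow <- 0
    while (a_hi < target_factor && grow < 8) {
      hi <- hi * 2; a_hi <- af(hi); grow <- grow + 1
    }
    if (a_hi < a_lo)
      stop("calibration failure: achieved factor not monotone in the rate parameter")
    if (a_hi < target_factor) {
      warning("target factor unreachable for jpeg2000; best achievable returned")
      return(codec_param("jpeg2000", hi, target_factor = target_factor,
                         achieved_subset = a_hi))
    }
    if (a_lo >= target_factor * (1 - tolerance)) {
      # already at or above target at the lossless-most end of the bracket
      return(codec_param("jpeg2000", lo, target_factor = target_factor,
                         achieved_subset = a_lo))
    }
    best <- list(r = hi, a = a_hi)
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      am <- af(mid)
      if (abs(am - target_factor) < abs(best$a - target_factor))
        best <- list(r = mid, a = am)
      if (abs(am - target_factor) / target_factor <= tolerance)
        return(codec_param("jpeg2000", mid, target_factor = target_factor,
                           achieved_subset = am))
      if (am < target_factor) lo <- mid else hi <- mid
    }
    warning("calibration tolerance not reached within max_iter; best parameter returned")
    return(codec_param("jpeg2000", best$r, target_factor = target_factor,
                       achieved_subset = best$a))
  }
  if (codec_id == "jpegxr")
    .stopf("codec unavailable: no JPEG XR backend in this build",
           class = "tomopress_codec_unavailable")
  stop("unknown codec_id: ", codec_id)
}

# every-kth projection subset, about 5% of frames but at least min_n
.calibration_subset <- function(projections, fraction = 0.05, min_n = 8L) {
  n <- dim(projections)[3]
  n_sub <- min(n, max(min_n, ceiling(fraction * n)))
  idx <- unique(round(seq(1, n, length.out = n_sub)))
  projections[, , idx, drop = FALSE]
}

#' Compress a whole projection dataset to a target factor
#'
#' Calibrates the codec parameter on a subset of the projection frames
#' (about 5%, at least 8 frames), then encodes every frame of the dataset
#' (darks, flats and projections, each frame independently) with that
#' parameter.
#'
#' @param dataset a `projection_dataset`.
#' @param codec_id `"bit_reset"` or `"jpeg2000"`.
#' @param target_factor requested compression factor.
#' @param tolerance,subset_fraction,min_subset calibration controls.
#' @return a `compressed_dataset`: per-group payload lists, the calibrated
#'   [codec_param()], byte totals and the achieved factor over the whole
#'   dataset.
#' @export
compress_dataset <- function(dataset, codec_id, target_factor,
                             tolerance = 0.02, subset_fraction = 0.05,
                             min_subset = 8L) {
  stopifnot(inherits(dataset, "projection_dataset"))
  subset <- .calibration_subset(dataset$projections, subset_fraction,
                                min_subset)
  codec <- calibrate(codec_id, target_factor, subset, tolerance = tolerance)
  payloads <- list(darks = .encode_frames(dataset$darks, codec),
                   flats = .encode_frames(dataset$flats, codec),
                   projections = .encode_frames(dataset$projections, codec))
  original_bytes <- dataset_raw_bytes(dataset)
  compressed_bytes <- sum(vapply(unlist(payloads, recursive = FALSE),
                                 length, numeric(1)))
  structure(list(payloads = payloads, codec = codec,
                 original_bytes = original_bytes,
                 compressed_bytes = compressed_bytes,
                 achieved_factor = original_bytes / compressed_bytes,
                 target_factor = target_factor,
                 frame_dim = dim(dataset$projections)[1:2],
                 geometry = dataset$geometry, config = dataset$config,
                 provenance = dataset$provenance),
            class = "compressed_dataset")
}

#' @export
print.compressed_dataset <- function(x, ...) {
  cat(sprintf("<compressed_dataset> %s(%.4g): target %.3g, achieved %.3f (%d -> %d bytes)\n",
              x$codec$codec_id, x$codec$parameter, x$target_factor,
              x$achieved_factor, x$original_bytes, x$compressed_bytes))
  invisible(x)
}

#' Decode a compressed dataset back to frames
#'
#' @param cd a `compressed_dataset`.
#' @return a `projection_dataset` holding the decoded 16-bit frames (the
#'   noise-free `ideal` sinogram of the source, if any, is not carried over).
#' @export
decode_dataset <- function(cd) {
  stopifnot(inherits(cd, "compressed_dataset"))
  r <- cd$frame_dim[1]; cc <- cd$frame_dim[2]
  structure(list(darks = .decode_frames(cd$payloads$darks, cd$codec, r, cc),
                 flats = .decode_frames(cd$payloads$flats, cd$codec, r, cc),
                 projections = .decode_frames(cd$payloads$projections,
                                              cd$codec, r, cc),
                 geometry = cd$geometry, config = cd$config,
                 provenance = sprintf("%s; decoded from %s(%.5g)",
                                      cd$provenance, cd$codec$codec_id,
                                      cd$codec$parameter),
                 ideal = NULL),
            class = "projection_dataset")
}
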