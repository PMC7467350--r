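# JPEG 2000 backend bridge.
#
# There is no JPEG 2000 binding for R in this stack, so frames are passed to
# a small Python helper using Pillow (which wraps OpenJPEG) through raw
# little-endian buffers on disk. One process call handles a whole batch of
# frames, so calibration and dataset compression pay the interpreter
# start-up cost only a handful of times.

.python_bin <- function() {
  opt <- getOption("tomopress.python")
  if (!is.null(opt)) return(opt)
  p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) return(NULL)
  p
}

.jp2_bridge_script <- function() {
  system.file("python", "jp2_bridge.py", package = "tomopress")
}

#' Is the JPEG 2000 codec backend available?
#'
#' @return `TRUE` if a Python interpreter with Pillow/OpenJPEG support is on
#'   the path, `FALSE` otherwise. The probe result is cached per session.
#' @export
jp2_available <- function() {
  cached <- .tomopress_env$jp2_available
  if (!is.null(cached)) return(cached)
  ok <- FALSE
  py <- .python_bin()
  script <- .jp2_bridge_script()
  if (!is.null(py) && nzchar(script)) {
    st <- tryCatch(system2(py, c(shQuote(script), "probe"),
                           stdout = FALSE, stderr = FALSE),
                   error = function(e) 1L, warning = function(w) 1L)
    ok <- identical(st, 0L)
  }
  .tomopress_env$jp2_available <- ok
  ok
}

.jp2_call <- function(mode, inpath, outpath) {
  py <- .python_bin()
  if (is.null(py))
    .stopf("jpeg2000 backend not available: no python interpreter found",
           class = "tomopress_codec_unavailable")
  st <- system2(py, c(shQuote(.jp2_bridge_script()), mode, shQuote(inpath),
                      shQuote(outpath)), stdout = FALSE, stderr = "")
  if (!identical(st, 0L)) .stopf("jpeg2000 codec backend failed (exit %d)", st)
  invisible(NULL)
}

# frames: integer array rows x cols x n (16-bit range); returns list of raw
.jp2_encode <- function(frames, rate) {
  d <- dim(frames)
  if (length(d) == 2) { frames <- array(frames, c(d, 1L)); d <- dim(frames) }
  inpath <- tempfile("jp2in"); outpath <- tempfile("jp2out")
  on.exit(unlink(c(inpath, outpath)), add = TRUE)
  con <- file(inpath, "wb")
  writeBin(as.integer(c(d[3], d[1], d[2])), con, size = 4, endian = "little")
  writeBin(as.double(rate), con, size = 8, endian = "little")
  writeBin(as.integer(frames), con, size = 2, endian = "little")
  close(con)
  .jp2_call("encode", inpath, outpath)
  con <- file(outpath, "rb")
  on.exit(close(con), add = TRUE)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  lapply(seq_len(n), function(i) {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    readBin(con, "raw", len)
  })
}

# payloads: list of raw; returns integer array rows x cols x n
.jp2_decode <- function(payloads, rows, cols) {
  inpath <- tempfile("jp2in"); outpath <- tempfile("jp2out")
  on.exit(unlink(c(inpath, outpath)), add = TRUE)
  con <- file(inpath, "wb")
  writeBin(as.integer(c(length(payloads), rows, cols)), con, size = 4,
           endian = "little")
  for (p in payloads) {
    writeBin(length(p), con, size = 4, endian = "little")
    writeBin(p, con)
  }
  close(con)
  .jp2_call("decode", inpath, outpath)
  raw <- readBin(outpath, "integer", n = rows * cols * length(payloads),
                 size = 2, signed = FALSE, endian = "little")
  array(raw, dim = c(rows, cols, length(payloads)))
}
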