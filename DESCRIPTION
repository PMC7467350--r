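Package: tomopress
Title: Impact of Lossy Projection Compression on Tomographic Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates parallel-beam synchrotron tomographic acquisitions
    (phantoms, photon and readout noise, dark and flat frames, 16-bit
    quantization), compresses the raw projections with a bit-reset plus
    bzip2 makeshift codec or with JPEG 2000 calibrated to a target
    compression factor by interval bisection, reconstructs volumes by
    filtered backprojection with optional single-distance Paganin phase
    retrieval, and quantifies the degradation of reconstructions from
    compressed data against the uncompressed ground truth using layer-wise
    streaming MSSIM statistics, compression curves, a plateau-drop safe
    compression factor criterion and region-based SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
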