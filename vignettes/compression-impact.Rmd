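---
title: "Assessing lossy projection compression with tomopress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing lossy projection compression with tomopress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Synchrotron tomographic microscopy beamlines store raw 16-bit projection
frames — darks, flats and sample projections — and scientific work happens on
the *reconstructed* volumes. Lossy compression of the raw frames is
attractive (lossless coding of photon-noise-dominated data saturates well
below 2x), but the question that matters is not how a projection looks after
compression; it is how much compression the *reconstruction* tolerates.
`tomopress` builds that assessment loop end to end: simulate an acquisition,
compress the raw frames to a controlled target factor, run the full
reconstruction pipeline, and quantify the difference against the
reconstruction from uncompressed data.

The package treats the reconstruction from uncompressed frames as ground
truth and measures only the *additional* error introduced by compression,
using the mean structural similarity index (MSSIM) accumulated over the
volume, plus a plateau-drop criterion that turns MSSIM-versus-factor curves
into a single *safe compression factor*.

## Acquisition model

`simulate_acquisition()` draws, per pixel,

```
counts = round( gain * Poisson(flux_I0 * flat(u, v) * exp(-L)) + N(dark_mean, dark_sigma) )
```

clipped to `[0, 65535]` (rounding is half-to-even). `L` are ideal line
integrals from a discrete Radon transform of a geometric phantom (ellipses,
annuli, a small strongly absorbing particle, resolved in painter's order).
Flat frames use `L = 0`, dark frames have zero flux. `flat(u, v)` is a smooth
low-order polynomial within about +-10% of unity, so flat-field correction is
exercised nontrivially. Poisson sampling happens in photon units with the
gain applied afterwards, readout noise is Gaussian.

Two fixed presets emulate the two beamline regimes at desk scale:

| preset | angles | detector | slices | flux (counts) | darks/flats | readout sd |
|--------|-------:|---------:|-------:|--------------:|------------:|-----------:|
| standard | 721 | 256 | 64 | 30000 | 10 / 40 | 10 |
| fast     | 181 | 128 | 32 |  2500 |  5 / 20 | 20 |

The standard flux puts the flat level near 30000 counts, where Poisson noise
(sd about 170 counts) dominates the low byte of every sample — the regime in
which lossless coding is structurally limited. The fast preset has 12x less
flux, fewer and smaller frames, and doubled readout noise, reproducing the
"fewer, smaller, noisier" contrast between the two dataset classes. These
sizes keep a full sweep (compress, decode, reconstruct, score, for every
codec and target factor) in the minutes range on one CPU; they are the
problem sizes used throughout the tests and the acceptance script.

What the generator deliberately does *not* model: Fresnel fringe formation
(phase retrieval is exercised as a processing stage on absorption-like
data), detector point-spread, ring artifacts, rotation-axis misalignment.
Passing tests therefore demonstrate correct propagation of *compression*
artifacts through the pipeline, not fidelity to every beamline nuisance.

## Codecs and calibration

Three codec identities sit behind one interface:

* `bit_reset` — zero the `n` least-significant bits of every sample
  (`floor(v / 2^n) * 2^n`, idempotent, systematically rounding down), then
  entropy-code the raw little-endian buffer with bzip2. Decoding is exact on
  the bit-reset image; `n = 0` is a byte-lossless archive.
* `jpeg2000` — OpenJPEG irreversible coding (through Pillow), parameterized
  by codestream rate.
* `jpegxr` — an optional adapter; with no backend present, encode/decode
  raise an explicit `codec unavailable` condition rather than falling back
  silently.

Compression is controlled by a *target factor*. `calibrate()` finds the
codec parameter by interval bisection of the achieved factor on a sample
subset (every k-th projection frame, about 5% of frames and at least 8 —
the subset composition is a documented choice, bounded so calibration stays
cheap). For the continuous JPEG 2000 rate the bisection stops within 2%
relative tolerance (20 iterations maximum, bracket grown from the parameter
extremes; a non-monotone bracket is a calibration error). The bit-reset
parameter is an integer, so the calibrated value is the largest `n_bits`
whose achieved factor does not exceed the target — the achieved factor is
"down-rounded" relative to the target, and each additional bit roughly
doubles the factor, which is exactly why this codec degrades abruptly past
its safe point. Darks and flats are compressed with the same calibrated
parameter as the projections, and the achieved factor is defined over the
whole dataset's raw bytes (2 per sample).

## Reconstruction

`reconstruct_pipeline()` chains:

1. **Flat-field correction** `T = (P - mean(darks)) / (mean(flats) -
   mean(darks))`, with means (not medians) over the calibration frames and a
   transmission floor of 1e-6 — noisy fast-preset pixels can go nonpositive
   after dark subtraction, and the floor keeps the logarithm defined while
   warning (0.1%) or rejecting (10%) when flats fail to exceed darks.
2. Either **negative logarithm** (Beer–Lambert inversion) or
   **single-distance Paganin phase retrieval**:
   `t = -(1/mu) ln( F^-1[ F(T) / (1 + (R delta / mu) |k|^2) ] )`,
   `mu = 4 pi beta / lambda`, with `|k|^2 = (2 pi u)^2 + (2 pi v)^2` on the
   mirror-padded (2x) detector grid to suppress FFT wrap-around. The filter
   has unit DC gain and is a strong low pass; its preset
   (`delta/beta = 100`, 20 keV, 30 mm propagation) is a typical
   single-distance setting, chosen here because the source experiments do
   not print theirs.
3. **Filtered backprojection**: the Kak–Slaney band-limited ramp kernel
   evaluated in the frequency domain (zero-padded to the next power of two
   past twice the detector width; optional raised-cosine apodization,
   default pure ramp), linear interpolation along the detector during
   backprojection, output masked to the reconstruction circle and scaled by
   `pi / (2 n_angles)` and the pixel size so a disk phantom reconstructs to
   its attenuation value. Slice centers sit at `(grid - 1) / 2`; angle 0
   projects along the first in-plane axis; the rotation axis is assumed
   centered (the generator guarantees it).

Everything downstream of the simulator is deterministic, so the pipeline
commutes bit-exactly with a lossless codec round trip — a property the test
suite asserts at full preset scale.

## Scoring and the safe factor

`mssim_volume()` evaluates volumes layer-wise: per slice an SSIM map with
the standard constants (`K1 = 0.01`, `K2 = 0.03`, 11x11 Gaussian window with
sigma 1.5, unit exponents), then a streaming fold of `(n, mean, M2)` moment
summaries using the pairwise update

```
delta = mean_b - mean_a
n     = n_a + n_b
mean  = mean_a + delta * n_b / n
M2    = M2_a + M2_b + delta^2 * n_a * n_b / n
```

so the evaluator never holds more than one slice's map — the same
merge-of-moments scheme used for single-pass parallel variance. Choices that
matter and their rationale:

* **Dynamic range** `L` is the max-minus-min over the *whole ground-truth
  volume*, not per slice and not over the pair: volume-wide because slices
  of one volume must share a scale, truth-only so `L` does not depend on the
  codec under test.
* **No downsampling**: the comparison targets machine-visible structure,
  not viewing-distance perception.
* **Windows fully inside the slice** (no padding): avoids edge bias; the
  per-slice pixel count `n` reflects the smaller map.
* **Population variance** `M2 / n`: a map is the full population of window
  positions, not a sample.

`compression_curve()` sweeps target factors and records
`(target, achieved, mssim, ssim_variance)` per point, with the *achieved*
factor as abscissa (bit reset quantizes factors coarsely, so the target is a
poor axis). A failed codec point is recorded as a missing row, never
dropped. `detect_safe_factor()` then finds the largest achieved factor still
on the initial plateau. Degradation is deliberately the *joint* event — an
MSSIM drop of more than 1% (relative) below the plateau mean occurring
together with an SSIM variance above 2x the plateau median variance; both
knobs are documented defaults of a criterion that is qualitative in origin.
Requiring concomitance matters in practice: the variance at near-lossless
points is vanishingly small, so on its own any real variance scale would
look like a catastrophic "rise" while the reconstruction is still visually
and numerically on its plateau. If the very first point is already degraded
there is no safe factor, and the detector says so explicitly.

`snr()` gives the complementary region-based measure
`(mean(signal) - mean(background)) / sd(background)` pooled over slices;
preset regions place the signal patch in the uniform matrix and the
background patch inside the reconstruction circle but outside the sample.

## Orchestration

`run_experiment()` ties the loop together from an `experiment_config()`:
simulate (or accept an explicit phantom/geometry/config triple), reconstruct
per-variant ground truths, sweep every codec over the target list
(compressing once per target and scoring all variants from the same decoded
frames), detect safe factors, and emit a JSON report, a CSV of curve points
and MSSIM +- SD figures. The default target sweep
`{1.5, 2, 3, 4, 5, 6, 8, 10, 12}` flanks both the expected plateau and the
drop region. Reports embed seed, package version and a config echo;
reruns with the same seed are byte-identical. Config validation is by
explicit field checks in the constructor. A thin command-line front end
(`inst/cli/tomopress`, verbs `simulate`, `compress`, `reconstruct`,
`evaluate`, `run`, `report`) wraps these functions for shell use.

```{r}
library(tomopress)
report <- run_experiment(experiment_config(
  preset = "standard", codecs = c("bit_reset", "jpeg2000"),
  target_factors = c(2, 3, 4, 6, 9, 12), seed = 42,
  output_dir = "standard_run"))
report$safe_factors
```

## Numerical and degenerate-input choices

* Transmission floor 1e-6 before any logarithm; `neg_log()` itself rejects
  nonpositive input (flooring is the caller's contract).
* FFT padding: mirror reflection to twice the frame for Paganin (even
  periodic extension, no seam), zero-padding to a power of two for the ramp
  filter.
* Quantization rounds half to even, then clips to `[0, 65535]`; a
  configuration whose expected flat level would saturate more than 1% of
  pixels is rejected up front.
* Overlapping phantom features resolve by painter's order (later feature
  wins) — simple, deterministic, and easy to oracle per voxel.
* A constant volume has no dynamic range and is rejected rather than given
  an arbitrary `L`.
* SSIM self-comparison returns exactly 1 (identical floating expressions in
  numerator and denominator), which the equality tests rely on.

## Known limitations

* The phantom family is geometric; real specimens' texture, and therefore
  the *absolute* safe factors found here, will differ — the package asserts
  orderings (standard vs fast, phase-retrieved vs absorption) rather than
  transferring absolute factors to beamline data.
* Phase retrieval is applied to absorption-contrast simulations; no Fresnel
  propagation is synthesized, so the retrieval stage acts as the strong
  low-pass it is, without edge-enhancement input.
* The reconstruction is plain FBP with a centered axis; gridrec-style
  Fourier reconstruction, ring removal and axis estimation are out of scope.
* JPEG XR has no available backend in this build; experiments run with the
  two mandatory codecs.
* Detector noise parameters are stand-ins chosen for realistic
  signal-to-noise contrast between regimes, not measurements of any
  specific hardware.
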