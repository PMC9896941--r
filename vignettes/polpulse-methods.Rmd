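---
title: "Methods: quality-controlled denoising and Pol II cluster dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality-controlled denoising and Pol II cluster dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpulse)
```

## Scope and model

`polpulse` implements a workflow for high-speed two-channel 3D fluorescence
microscopy of RNA polymerase II (Pol II) clusters, phosphorylated at Ser5
(recruited/initiating polymerase) or Ser2 (elongating polymerase) of the
C-terminal domain. The workflow has four computational stages:

1. **Image-quality metrics.** Fourier ring correlation (FRC) with
   effective-resolution extraction, and the structural term of SSIM with a
   local error map.
2. **Two-phase acquisition with a QC gate.** Phase A records, per z plane,
   one low-quality image, two high-quality references and two low-quality
   test images; phase B records only the fast low-quality time-lapse. A
   pluggable denoiser is judged on the phase-A test pair before it may be
   applied to phase B.
3. **Cluster segmentation, shape and tracking.** 3D segmentation of the
   Ser5P channel, per-cluster intensities, elongation and solidity, and
   proximity tracking, followed by elongation-anchored time-shifted
   cross-correlation with a track bootstrap.
4. **Pseudo-time for fixed samples.** Gene--cluster interaction pairs,
   PCA of their standardized feature vectors, an angular pseudo-time
   coordinate `s = atan2(PC2, PC1) / 2π ∈ [0, 1)`, register-shift
   correlations, and the interaction-cycle duration estimate.

Everything is exercised end-to-end on synthetic data with known ground
truth; no real acquisitions ship with the package.

## Quality metrics

**SSIM structural term.** We use only the covariance component of SSIM,

\[ s(x, y) = \frac{2\sigma_{xy} + C}{\sigma_x^2 + \sigma_y^2 + C}, \qquad
   C = 2 c_3, \]

computed over uniform local windows (default 7×7, truncated at borders so
the map matches the input size) and averaged. This form is symmetric,
bounded in [−1, 1], exactly 1 for `y = x`, and invariant to adding a
constant to either image. A frequently printed variant divides by
\(\sigma_x \sigma_y\); that form does not satisfy \(s(x,x)=1\) and is not
used here. The stabilizer defaults to \(c_3 = (0.03 L)^2 / 2\) with \(L\)
the joint dynamic range — the conventional SSIM constant; it also keeps
constant windows well-defined.

**FRC.** \( \mathrm{FRC}(r) = \mathrm{Re}\,\sum_{r_i \in r} F_1 F_2^* \,/\,
\sqrt{\sum |F_1|^2 \sum |F_2|^2} \) over annuli of integer frequency-pixel
radius (nearest-ring binning, configurable bin width). Numerical choices:

* the real part of the complex numerator (standard practice);
* a Tukey taper (α = 0.25, `window_fn = "none"` available) before the
  transform to suppress edge leakage on real images. The taper smears a
  sharp band edge by a few rings, so tests on the *periodic* synthetic
  band-limited fixture use `"none"`;
* non-square inputs are center-cropped with a warning;
* effective resolution is `1/f*` at the first crossing below the 1/7
  threshold, linearly interpolated between the bracketing rings; a curve
  that never crosses is "unresolved at Nyquist" and carries the bound
  `2 × pixel size`; a curve starting below threshold is "unresolvable",
  a result, not an error;
* no curve smoothing before thresholding (an optional moving average is
  out of scope for the default path);
* 3D stacks are evaluated per xy-plane (lateral resolution); the
  per-position value is the median over signal planes, or the central
  plane for the QC gate default.

## The QC gate

Thresholds (`min_resolution_nm`, `min_ssim`, `max_local_error_fraction`,
`local_ssim_floor`) are mandatory: the required resolution is an
experimental choice, and silent defaults would hide it. The gate
reconstructs the two phase-A test images, computes FRC resolution on the
reconstructed pair, SSIM against a high-quality reference, and the share
of the local SSIM map below the floor. Any metric failure rejects with
reason `metric-error` — never a silent accept. The decision is a pure
function of the stored numbers (`qc_recheck()` re-derives it), and phase-B
frames never enter the metrics. The denoiser is a contract
(same-shape, deterministic); shipped baselines are identity, Gaussian and
median filters. Reimplementing the blind-spot network is deliberately out
of scope — the contribution this package captures is the QC workflow
around a denoiser, not the denoiser itself.

## Synthetic scenes

Clusters are rendered as *bent* ellipsoids: straight ellipsoids are convex
and cannot vary in solidity, so the solidity cycle is driven by a
quadratic bend of the major axis (bend amplitude up → solidity down).
Per cluster, a random phase φ and three coupled sinusoids with the
package's stated lags:

* Ser5P intensity peaks first (`cycle_period_s = 36`, the one cycle
  duration the underlying analysis quotes);
* Ser2P intensity follows `lag_ser2p_s = 5` s later;
* the shape excursion (elongation up to `elongation_max = 2`, bend up to
  `bend_max = 0.6`) follows `lag_shape_s = 10` s after Ser5P.

Volumes default to 16×96×96 voxels of 200×100×100 nm (z twice as coarse,
as in typical confocal stacks), 2 s frame interval, background 10 and
peak signal 100 photons per reference exposure, and a light Gaussian blur
(σ = 150/80/80 nm) standing in for the optical transfer — no full PSF
model, no photobleaching. The camera model is Poisson shot noise on the
exposure-scaled signal, gain, constant offset, and Gaussian read noise —
the canonical sCMOS model, satisfying the pixelwise-independence
assumption blind-spot denoisers require. Gain and read noise are
documented placeholders (defaults 1 count/photon, 2 counts), not fitted
to any instrument.

The generator records exact ground truth (labels, phases, centroids,
axes, bend, true intensity and shape drivers), so recovery tests never
rely on re-measuring the synthetic image by the same code path under
test.

What a green test does *not* establish: the synthetic world has
axis-aligned clusters, stationary centroids, sinusoidal cycles and
spatially uniform background — real nuclei have none of these, so passing
tests validate the computational machinery, not biological claims.

## Segmentation, shape, tracking

Segmentation is Gaussian smoothing (σ = 1 px), a global Otsu threshold
(a quantile threshold is available; Otsu can drop a dim cluster when
another is much brighter — visible in the tests), 26-connected components
and a minimum volume. Elongation is
\(\sqrt{\lambda_{max}/\lambda_{min}}\) of the physical-unit covariance of
voxel coordinates with per-voxel box moments (edge²/12) added — this
removes most discretization bias for small regions; coplanar regions are
evaluated on the non-degenerate subspace and flagged. Solidity follows
the regionprops convention: region voxel count divided by the count of
voxels whose centers fall inside the convex hull of the region's voxel
centers (exactly 1 for a filled cuboid). The hull is an own incremental
quickhull, cross-checked against a plane-enumeration oracle, because no
qhull binding is available in the target environment. One known bias:
anisotropic blur plus thresholding inflates masks more along z than xy,
which offsets absolute elongation upward; the temporal modulation that
the correlation analyses consume is preserved.

**Mask means and the boundary-dilution bias.** The mean intensity inside
a segmentation mask of blurred data includes a partial-intensity shoulder
whose share tracks the cluster's surface area — so it oscillates with the
*shape* cycle, not the intensity cycle, and a camera offset amplifies the
effect (the raw mask mean then mostly measures how much dim boundary the
mask includes). On synthetic scenes this measurably drags the apparent
Ser2P lag from 5 s toward the 10 s shape lag. `measure_clusters()`
therefore offers `background_subtract` (median outside all labels) and
`erode_mask`: the intensity-measurement mask is eroded by the shoulder
width — two 6-neighbor steps for the default σ ≈ 1 px optical blur plus
~1 px denoiser smoothing — while shape, volume and centroid always use
the full mask. The defaults leave both off, which reproduces the naive
measurement and its bias; the demo pipeline and the end-to-end tests
turn both on.

Tracking is greedy mutual-nearest-neighbor linking between consecutive
frames with a mandatory linking radius and optional gap bridging
(default 0) — "spatial proximity in consecutive time points" with minimal
machinery, no global assignment solver.

## Cross-correlation and bootstrap

Per track, series are z-scored (Pearson correlations are then invariant
to per-track affine intensity transforms) and correlated at integer-frame
lags over the valid overlap only; lags with fewer than 3 overlapping
points are missing, not zero. Positive lag means the signal's event
follows the anchor's. The default anchor is elongation; the end-to-end
lag-recovery tests anchor on Ser5P intensity because the generator's lags
are defined relative to it. The bootstrap resamples whole tracks
(preserving within-track autocorrelation), 1000 resamples, percentile
2.5/97.5 band clipped to contain the mean. Extrema ties break toward the
smallest |lag|, then the negative lag. Detrending is available but off by
default (the underlying analysis does not state it).

## Pseudo-time

Features (gene intensity, cluster Ser5P/Ser2P means, gene–cluster
distance, elongation, solidity) are z-scored before PCA — their units are
incommensurable. `s = atan2(PC2, PC1)/2π`, wrapped into [0, 1) by adding
1 to negative values. The coordinate is defined only up to rotation and
reflection of the PC plane; recovery is therefore scored with the
Fisher–Lee circular correlation, whose absolute value is gauge-invariant,
and the reflection gauge is tested explicitly (reversing PC2 reverses the
circular order and mirrors register-shift extrema). Aggregation note: the
25%-noise recovery criterion is evaluated as the mean circular
correlation across ≥10 generator seeds. Register shifts are circular
(s is periodic); profiles may be smoothed with a circular moving average
(default window max(5, n/40)). A reliability check flags genes whose
contact fraction within a radius is too low before pseudo-time is
attempted — for rarely contacting genes the reconstruction is known to
fail. One caveat established by the tests: with asymmetric feature phase
offsets the noise-free PC-plane image is an ellipse, not a circle, so
recovery is near-exact (|ρ| ≈ 0.98) rather than exact; with symmetric
offsets it is exact to sampling precision.

The cycle-duration estimate divides the seconds spanned by the
register-shift distance between the Ser5P correlation extrema by that
distance in data points, and multiplies by each gene's total pair count:
with counts 169/186/191 and 50 steps ≡ 10 s this gives 33.8/37.2/38.2 s,
mean ≈ 36 s between consecutive gene–cluster interactions.

## Pipeline and provenance

`run_pipeline()` exposes `simulate`, `qc`, `reconstruct`,
`segment-track`, `fluctuation`, `pseudotime`, `all` over one YAML/JSON
config. Every stage writes a manifest (config MD5, seed, package version,
inputs/outputs); downstream stages refuse inputs without one unless
`no_provenance`. Reconstruction of a QC-rejected position requires an
explicit, logged override. TIFF I/O is a minimal baseline implementation
(little-endian, uncompressed, 16-bit unsigned or 32-bit float, multi-page,
JSON ImageDescription with axes T,Z,C,Y,X and voxel size) written for
this package because no TIFF-capable R package is available in the target
environment; files are readable by standard readers (verified against
`tifffile` during development).

## Determinism

Every stochastic operation takes an explicit integer seed and restores
the caller's RNG state; sub-seeds are derived arithmetically and kept
below 2³¹. Identical config + seed reproduces every artifact bit-for-bit
(the test suite asserts byte-identical TIFF and CSV outputs).

## Known limitations

* No blind-spot network, GPU path, deconvolution, or microscope control.
* No nucleus segmentation; no cluster split/merge resolution; no
  sub-voxel localization.
* FRC is lateral (plane-wise) only; no 3D shell correlation.
* The synthetic world is a stated fixture, not a fitted model of any
  instrument.
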