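---
title: "Methods: two-colour FRAP quantification in frapquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-colour FRAP quantification in frapquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapquant)
```

## The measurement problem

In a two-colour FRAP experiment a centrosome is photobleached and the
return of two spectrally distinct fusion proteins is imaged over time. Two
quantities matter. First, the *spatial offset* between the recovering
green and red signal centres: sub-resolution displacements of
0.05–0.25 µm discriminate whether two proteins return to the same
structure (e.g. around the mother centriole) or to different ones (e.g.
the growing daughter centriole). Second, the *recovery kinetics*: the
normalised intensity in a fixed region over time, whose shape (immediate
vs delayed onset) reports when recruitment is possible in the cell cycle.

Both measurements are smaller than, or comparable to, two confounders
that the pipeline removes explicitly: chromatic/mechanical channel
misalignment of the microscope (order 0.05 µm), and the pixel quantisation
of a 0.105 µm camera grid.

## Model and procedure

**Channel registration.** Sub-resolution multi-colour beads emit in both
channels, so any displacement between their green and red images is
instrumental. For matched bead pairs the model is
`r_i = g_i + s + e_i`, with `s` the systematic shift and `e_i` per-bead
localisation noise. We estimate `s` as the mean *displacement vector*
pooled over all beads and calibration images with equal weight, and report
its magnitude `|s|`. Averaging the scalar distances `|r_i − g_i|` instead
would be biased upward (a folded statistic) and could not correct
direction, so the vector mean is the only estimator that can actually be
subtracted from coordinates. Matching is mutual-nearest-neighbour within
0.3 µm; this radius is an order of magnitude below typical bead spacing
and several times the largest shift of interest, so mismatches are
essentially impossible and chaining errors cannot occur. Correction is the
pure function `position_red − s`. Because the printed precision of such
calibrations (± a few nm) could be either an SD or an SEM, the model
records both (`sd_um`, `se_um`).

**Sub-pixel localisation.** Each signal is localised on the most central
z-plane of the centrosome — operationalised as the slice with the largest
summed intensity in the analysis window, ties to the lowest index, since
no sharper criterion is available — after 5× upscaling (bilinear; each
pixel divided into 5 × 5). The centroid is the intensity-weighted mean of
pixels above a threshold. The threshold is background + 50% of the
background-subtracted window maximum, with background taken as the mean of
the dimmest quartile of window pixels: deterministic, scale-free, and
unbiased for unimodal symmetric spots. Both the fraction and the
background estimate are exposed in `threshold_rule()` because the original
tooling's exact threshold is not recoverable; tests show the default
recovers simulated offsets without measurable bias.

**Offset.** Green and red are localised independently; red is corrected by
the registration model; the displacement is reported with red at the
origin, and the per-centrosome distances are averaged. A measured distance
is non-negative, so at zero true offset the expectation equals the folded
localisation noise, not zero: the calibrated noise floor of the default
scenes is below 0.02 µm, and the null acceptance test uses that floor.

**Radial profiling.** Ring `k` collects pixels whose centre radius falls
in `[k·0.028, (k+1)·0.028)` µm out to 3.02 µm (108 rings), on the
upscaled image so rings are finer than pixels; ring means use pixel-centre
assignment without area weighting, and the oracle test bounds the
resulting discretisation error at 2% against dense annulus integrals.
Profiles are background-subtracted, peak-normalised to exactly 1, then
mirrored about r = 0 (the one measured side reflected, central ring
counted once — a display convention, not an independent measurement).
Averages require at least 10 centrosomes per channel, and the red
profile's axis is shifted by the measured mean offset when the two
channels are displayed together.

**Recovery curves.** The ROI is every reference-channel pixel above the
frame mean + 2 SD, computed by default on the maximum-intensity projection
of the last pre-bleach frame (whether the original rule used slices or
projections is not stated; the projection is the default and the frame is
configurable). Per timepoint and channel the ROI sum minus (local
background per pixel × ROI size) is normalised by the pre-bleach mean, so
pre-bleach values average 1. "Local cytoplasmic background" is
operationalised as the mean in a 1.8–2.4 µm annulus around the centrosome
— far enough out that PCM tails are negligible, close enough to track
local cytosol — because no region is prescribed; it is a configurable
argument everywhere it is used.

**Focus statistics.** With two pre-bleach centriolar foci and a reference
toroid that surrounds only the mother centriole, the focus nearer the
toroid centre is the mother; "inside the toroid" is deliberately reduced
to this distance rule rather than fitting the toroid's radius, because the
downstream comparison is entirely in terms of distances. Distance
differences below the localisation noise floor are flagged ambiguous.
Group comparisons report box statistics (25th–75th percentile boxes,
min–max whiskers, median and mean) and two-sided tests of the post-bleach
group against each pre-bleach group. The default test is the Mann–Whitney
U — distances are non-negative and right-skewed — with Welch's t and a
permutation test available; the test used is always recorded, and the
original study's printed p-values are not treated as reproducible targets
since its test is unreported.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
with acquisition defaults fixed to the stated imaging conditions:
0.105 µm pixels, 5 z-slices 0.5 µm apart analysed as maximum projections,
frames spanning pre- and post-bleach, bleach at t = 0.

* **PSF**: isotropic 2-D Gaussian per slice (σ = 0.1 µm, roughly the
  diffraction limit of a 1.4 NA objective at ~500 nm), rendered by exact
  pixel integration (difference of normal CDFs), so flux is conserved to
  <1% at any sub-pixel position. Axial behaviour is a Gaussian amplitude
  decay (σz = 0.6 µm) — not 3-D optics, which the projection-based
  analysis never sees.
* **Noise**: Poisson(signal + background) plus Gaussian read noise at
  gain 1, the standard sCMOS/EMCCD approximation. The default photon
  budget (2000 photons/bead, background 10, read noise 2) gives single-bead
  localisation noise of a few nm, so a 977-bead calibration resolves the
  ±0.005 µm scale; it was chosen once from that requirement, not tuned to
  any test outcome.
* **Bead fields**: beads on a jittered grid with ≥4σ separation (so
  matching is unambiguous); red = green + systematic shift + per-bead
  jitter (default sd 0.03 µm).
* **Centrosome scenes**: a broad PCM Gaussian (σ = 0.35 µm, necessarily
  broader than the PSF) in green and tight centriolar foci in red; after
  the bleach both drop to background and recover as
  `I(t) = f·(1 − e^{−kt})` (defaults f = 0.8, k = 0.03 s⁻¹, giving the
  observed substantial-but-incomplete recovery by 60–90 s). The recovering
  red focus is displaced from the PCM centre by the truth offset; an
  optional red-channel delay reproduces the two-phase kinetics seen when
  recruitment only resumes at a cell-cycle transition; an optional linear
  growth of the PCM σ emulates "recovers centrally, then spreads" as a
  rendering convenience, not a mechanistic model.
* **Reproducibility**: one top-level seed per scene; generators use a
  private RNG stream and restore the caller's; identical spec + seed is
  bit-identical.

What a green test does *not* establish: the generator has no cell motion,
no focus drift, no uneven illumination, no autofluorescence, no depth- or
wavelength-dependent PSF asymmetry, and its PCM is a symmetric Gaussian
rather than a structured scaffold. Parameter recovery here validates the
*measurement chain*, not robustness to every real-world artefact.

## Numerical choices

* Coordinates are continuous, in µm, origin at the centre of pixel (0,0),
  row-major and 0-based in formulas; upscaled coordinates map back through
  `x_in = (u + 0.5)/f − 0.5`, so centroids measured at factor f are
  directly comparable across factors.
* TIFF storage is 16-bit unsigned, values rounded and clamped on write;
  integer payloads round-trip bit-exactly. Page order is channel-fastest,
  then z, then time, and calibration lives in a JSON sidecar that is never
  silently defaulted. (The TIFF codec is a minimal uncompressed baseline
  implementation because the deployment environment provides no R TIFF
  reader; anything fancier errors loudly.) Scene configs for the CLI are
  JSON for the same reason — no YAML parser is available offline.
* Ties in central-slice selection break to the lowest index; empty radial
  rings are `NA`, never 0; degenerate (all-equal) statistical groups skip
  the test with a notice rather than fabricating a p-value.
* The 200-calibration unbiasedness property runs at 40 beads per
  calibration (SE ≈ 0.005 µm each) rather than 977 to stay inside the
  test-time budget; the full-size 12-image/977-bead recovery is asserted
  separately at the stated 0.005 µm tolerance.

## Known limitations

A single translation models the channel misalignment (no rotation, scale,
or field-dependent distortion); windows are supplied rather than tracked;
distances are 2-D projections; recovery curves are reported raw, with no
kinetic model fitting. These match the scope of the measurements the
pipeline is designed to reproduce.
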