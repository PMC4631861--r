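# frapquant

Quantitative analysis of **two-colour FRAP** (fluorescence recovery after
photobleaching) microscopy, built for the centrosome-biology use case:
after bleaching a centrosome in a living embryo, where — and how fast —
does each fluorescently tagged protein come back?

The scientific problem is that the answer lives below the pixel scale.
Recovering green (e.g. a pericentriolar-material protein) and red (e.g. a
centriolar protein) signals can sit only ~0.2 µm apart — two pixels on a
typical spinning-disk system — and the microscope itself misaligns the two
colour channels by a comparable amount. `frapquant` implements the full
measurement chain that makes such offsets trustworthy:

1. **Channel registration** — sub-resolution fiducial beads appear in both
   channels; the mean red−green displacement *vector* over hundreds of
   beads, `s = mean(r_i − g_i)`, estimates the systematic misalignment
   (magnitude of order 0.05 µm) and is subtracted from every red
   coordinate.
2. **Sub-pixel localisation** — each recovering signal is localised on the
   most central z-plane by 5× upscaling followed by a thresholded centre
   of mass, `c = Σ I(p)·p / Σ I(p)` over pixels above threshold.
3. **Offset measurement** — the corrected green−red displacement per
   centrosome, with the red signal at the origin, and its average over
   centrosomes.
4. **Radial profiling** — ring-averaged intensity vs radius (0.028 µm
   rings spanning 3.02 µm), background-subtracted, peak-normalised to 1,
   and mirrored about r = 0 for display; green and red profiles are plotted
   offset by the measured mean displacement.
5. **Recovery curves** — per-timepoint ROI sums (ROI = reference-channel
   pixels above mean + 2 SD), background-subtracted and normalised to the
   pre-bleach mean.
6. **Focus statistics** — mother/daughter centriole assignment by distance
   to a reference toroid centre, with box-plot summaries and two-sided
   Mann–Whitney comparisons.

Because real FRAP microscopy data are rarely shareable, the package ships a
**synthetic-microscopy generator** (integrated-Gaussian PSF, Poisson shot
noise, Gaussian read noise, known ground truth) so the entire pipeline is
validated by parameter recovery.

## Worked example

Calibrate the channels from 12 simulated bead fields (977 beads, true
shift 0.058 µm), then measure a simulated 0.21 µm green–red offset from 10
centrosome FRAP series:

```r
library(frapquant)

cal <- simulate_bead_calibration(true_shift_um = c(0.058, 0), seed = 1)
cal$model
#> RegistrationModel: shift (0.0571, -0.0009) um, |shift| = 0.0571 um
#>   965 beads from 12 image(s); magnitude sd 0.0276 um, se 0.0009 um

res <- simulate_offset_experiment(0.21, n_series = 10, seed = 2,
                                  model = cal$model,
                                  camera_shift_um = c(0.058, 0))
res$mean_distance_um
#> mean corrected distance: 0.211 um (sd 0.005, n = 10)
head(res$table, 3)
#>   id      dx_um       dy_um distance_um t_s
#> 1  1  0.2141527 0.007079284   0.2142696  60
#> 2  2  0.1047826 0.180290454   0.2085283  60
#> 3  3 -0.2056066 0.067317244   0.2163462  60
```

The registration model recovers the simulated 0.058 µm misalignment to
within ~1 nm of its standard error; the corrected per-centrosome distances
(`table`) average 0.211 µm against a 0.21 µm truth — the displacement
direction is random per centrosome (`dx_um`, `dy_um`), but the distance is
recovered. Lower-level functions (`generate_frap_series()`,
`measure_pair_offset()`, `radial_profile()`, `recovery_curve()`,
`assign_foci()`, …) expose each stage; images round-trip to multi-page
TIFF with JSON sidecar metadata via `write_series()` / `read_series()`.

## Command line

An installed `inst/cli/frapquant` script dispatches the subcommands
`simulate`, `register`, `offset`, `profile`, `recovery`, `foci`
(JSON configs in, CSV/JSON results out); see `?frap_cli`.
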