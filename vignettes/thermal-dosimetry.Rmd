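---
title: "PRFS thermometry and CEM43 dosimetry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRFS thermometry and CEM43 dosimetry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodose)
```

# What this package computes

`thermodose` implements the computational tail of an MR-guided interstitial
ultrasound ablation: wrapped-phase image time series go in, predicted
necrotic-zone volumes and method-comparison statistics come out. The chain is

1. **PRFS thermometry** — phase differences against a pre-heating baseline,
   background-field drift correction, conversion to temperature change;
2. **CEM43 dosimetry** — Sapareto–Dewey accumulation of cumulative equivalent
   minutes at 43 °C, thresholding, pixel-count volumetry and isodose contours;
3. **histology volumetry** — slab volumes from traced section areas, the way
   planimetry on stained brain sections is done;
4. **agreement analysis** — Bland–Altman limits of agreement, Pearson
   correlation, paired *t*, and mean ± SEM metric summaries;
5. **a synthetic-acquisition simulator** — a Pennes bioheat model with a known
   ground truth, so 1–4 are testable end to end without any imaging data.

# The PRFS model

Water-proton resonance frequency falls approximately linearly with
temperature, so in a spoiled gradient-echo acquisition the image phase is a
thermometer:

$$\Delta T(x,y) \;=\; \frac{\Delta\phi_w(x,y) - \Delta\phi_{cor}(x,y)}
{\gamma\,\alpha\,B_0\,TE},$$

where $\Delta\phi_w$ is the wrapped phase difference between a dynamic frame
and the baseline, and $\Delta\phi_{cor}$ is the background (drift) phase
estimated in tissue known not to be heated. Defaults: $B_0 = 3$ T,
$TE = 13.2$ ms, $\alpha = -0.01$ ppm/°C (the nominal aqueous-tissue
coefficient; it is not calibrated per subject), $\gamma = 2\pi \cdot
42.576\times 10^6$ rad/s/T. With these constants one degree of heating moves
the phase by $-0.106$ rad — heating makes the corrected phase *more negative*,
and the negative $\alpha$ in the denominator restores the sign.

Assumptions worth stating: aqueous tissue only (no fat correction), no motion
(phase differences are taken pixelwise), single-echo phase, and a baseline
that is genuinely pre-heating. The baseline is the *circular mean* of all
declared baseline frames; the count is configuration (`baseline_frames`,
default 2 in the simulator) because averaging reduces baseline noise and the
procedure is otherwise insensitive to it.

## Drift correction

The static field drifts on the minutes scale of a sonication, adding a
spatially smooth spurious phase. The referenced method fits a 2nd-order 2-D
polynomial to the phase-difference map over a **reference ring**: the outer
3-pixel shell of the brain mask (`make_edge_reference()`, morphological
erosion with a 3×3 element), chosen because the brain edge is far from the
applicator and so unheated. The fitted surface, evaluated over the whole
slice, is $\Delta\phi_{cor}$. Order 2 is the default because, on simulated
data with quadratic drift, it minimises the baseline-frame temperature
standard deviation against orders 1 (underfit: drift leaks into the maps) and
3 (no material gain, slightly worse extrapolation off the ring) — the suite
asserts exactly this.

Fits are per slice, on coordinates normalised to $[-1, 1]$ for conditioning,
by dense least squares (`stats::lm.fit`); a rank-deficient design (degenerate
ring geometry, e.g. a single row) is an error, not a warning.

## The referenceless fallback

If the subject moves, baseline subtraction is invalid. The fallback unwraps
each phase-difference map with the Goldstein branch-cut algorithm, fits a
4th-order polynomial to the *unwrapped* phase on the same edge ring, and
subtracts it as the background. The unwrapper's arbitrary global $2\pi k$
offset is absorbed by the polynomial's constant term. Goldstein specifics:
residues are detected on 2×2 loops; opposite charges are paired greedily by
nearest neighbour (ties in row-major order — deterministic); unpairable
residues are cut to the nearest border; integration is a flood fill that
cannot cross cut pixels; cut pixels and regions isolated by cuts are flagged
rather than trusted.

# CEM43 dosimetry

Thermal damage integrates temperature history into equivalent minutes at
43 °C:

$$\mathrm{CEM43} = \sum_t R^{\,43 - T_t}\,\Delta t,\qquad
R = \begin{cases}0.25 & T_t < 43\,^\circ\mathrm{C}\\
0.50 & T_t \ge 43\,^\circ\mathrm{C}\end{cases}$$

with $\Delta t$ in **minutes** and $T_t$ the average of the two adjacent
frames' absolute temperatures (trapezoid-style; $R$ is switched on that
average). Absolute temperature is `baseline_temp_C + ΔT` with the baseline a
*declared* parameter (default 37 °C) — interstitial thermometry measures
changes, not absolutes.

The necrotic zone is `CEM43 > 70` — strictly greater, an empirical soft-tissue
threshold (literature spans roughly 50–240). Volume is raw pixel counting
times the three voxel dimensions; deliberately no interpolation, no
connectivity filtering, no partial-volume modelling, so a 100-pixel zone at
0.586 × 0.586 × 5 mm voxels is exactly 0.172 cm³. Isodose contours are
marching squares (`grDevices::contourLines`) in physical mm, for display and
cross-checking only — volumetry never goes through contours.

# Histology volumetry

Traced section areas (cm²) arrive as a table; tracing itself is manual and out
of scope. Volume is $\sum_i A_i \cdot h$ over sections where the lesion goes
*through* the posterior face of the slab ($h$ = 0.5 cm by default). A lesion
that does not reach the posterior face contributes 0 by default — the honest
reading of the through-the-slab rule — with an optional `partial_fraction` for
users who prefer a half-slab credit. Scale calibration is pixels-per-cm from a
ruler line; areas convert as $\mathrm{px}^2 / \mathrm{scale}^2$.

# Agreement statistics

`bland_altman(a, b)` takes differences $a - b$ (convention: histology minus
MRTI), uses the $n-1$ sample SD, and reports limits of agreement
$\bar d \pm 1.96\,s_d$ with the fixed 1.96 multiplier (not a *t* quantile).
The percent difference divides by the grand mean of all $2n$ measurements —
the only convention consistent with the worked example in the README.
`paired_t` is the classical $t = \bar d/(s_d/\sqrt n)$ with $n-1$ degrees of
freedom, two-sided; `correlation` reports Pearson $r$, $r^2$ and the OLS line
of $b$ on $a$. All three are authored closed forms, tested against
`stats::t.test`, `stats::cor` and `stats::lm` as independent oracles.

# The synthetic acquisition

The simulator solves a Pennes-style bioheat equation for the temperature rise
$u = \Delta T$:

$$\frac{\partial u}{\partial t} = \kappa \nabla^2 u - w\,u + Q(x, t)$$

by explicit finite differences on the imaging grid, with insulated
(zero-flux) boundaries — the simplest condition with a testable conservation
law (with $w = 0$ and the source off, the spatial sum is conserved to 1e-6
relative; the suite asserts it). The solver sub-steps between frames to
satisfy the explicit stability bound
$\Delta t \le 1/(2\kappa \sum_d h_d^{-2} + w)$; a user-forced step that
violates it is an error naming the bound.

**Source model.** The applicator is a cylinder segment (radius 0.75 mm,
active length 7 mm along the slice axis). In-plane deposition follows the
cylindrical spreading of an interstitial source,
$(r_0/r)\,e^{-\mu (r - r_0)}$ with $\mu = 0.07$ Np/mm (an effective intensity
attenuation for brain near 7 MHz), flat inside the probe, and truncated to
exactly zero beyond 15 mm, where it has fallen below ~2% of peak — far-field
deposition below the thermometry noise floor would otherwise contaminate the
edge reference ring and break the exact round-trip contract. The 180° sector
pattern masks deposition to a half-plane at **twice** the circumferential
intensity: the transducer's full power exits through half the window.

**Tissue parameters.** $\kappa = 0.13$ mm²/s and $w = 0.008$ s⁻¹ are
literature-scale brain values, fixed once; with them a 3 W / 120 s sonication
returns to within 1 °C of baseline about 120 s after shutoff, inside the
90–180 s range the in-vivo recordings show. Baseline temperature 37 °C is a
declared configuration value, not a measurement.

**Calibration.** `sonication_power_scale` (peak heating rate per acoustic
watt, 0.30 °C/s/W) was calibrated *once* so that the 3 W / 120 s default
peaks near the reported ~8 °C ROI-mean rise (it lands at 11.0 °C, inside the
8 ± 4 °C band, with a 3 mm-radius probe-centred ROI), and is never refit.
Across the studied 3–6 W, 100–180 s envelope the simulator spans ROI-mean
peaks of ~10.6–23.2 °C against the reported 8–23 °C.

**Corruption model.** Rendered phase is
$\mathrm{wrap}(\gamma\alpha B_0 TE\,\Delta T + \text{drift}(t) + \varepsilon)$:
the drift is a 2nd-order spatial polynomial whose coefficients ramp linearly
in time (matching the correction model the thermometry must invert — by
design, so drift rejection is testable), and $\varepsilon$ is additive
Gaussian phase noise (the high-SNR limit of Rician magnitude noise; phase is
what PRFS consumes). Same seed and config give bit-identical series.

**Synthetic histology** resamples the true necrosis mask onto 5 mm slabs with
exact partial-volume overlap, so noise-free section volumes sum to the true
necrosis volume to within one resampling quantum; multiplicative Gaussian
area noise emulates tracing variability. The generator only emits
through-slab sections; partial-thickness tables are constructed by hand in
tests.

## What a green simulator test does not establish

The generator emulates geometry, timing, drift, and phase noise — not
susceptibility artifacts from the applicator, motion, perfusion
heterogeneity, tissue-property changes during coagulation, or k-space /
reconstruction effects. Recovery of ground truth within 15% here validates
the *pipeline's* internal consistency at realistic noise, not in-vivo
accuracy. One known tension in the emulated world is worth naming: a
sonication whose ROI-mean rise peaks at only 8 °C above a 37 °C baseline
cannot physically accumulate CEM43 > 70 over several-mm radii in two minutes,
so simulated necrosis volumes at matched ROI-mean rises are smaller than the
in-vivo volumes reported for such settings; the end-to-end check is therefore
a relative (estimated vs true) comparison, as it should be.

# Numerical choices and degenerate inputs

* Angles are radians in $(-\pi, \pi]$ everywhere; wrapping is
  `atan2(sin, cos)`, and phase differences use the complex-ratio angle, so
  wrap-around is exact.
* Time is seconds internally; dose accumulation converts to minutes.
* `roi_mean_curve` defines time-to-baseline as the first post-sonication
  frame at which the ROI mean is ≤ 1 °C (ε configurable); a curve that never
  returns yields `NA` with a warning rather than a fabricated time.
* A dose pixel exactly at the threshold is excluded (strict `>`).
* Empty ROIs, empty masks, rings that erode away, rank-deficient drift fits,
  fewer than two frames, and mismatched series lengths are all errors that
  name the violated requirement.

# Limitations

Single-echo aqueous-tissue PRFS only; no motion correction; no acoustic wave
propagation or transducer modelling beyond the sector-pattern source; no
DICOM ingestion (NIfTI + JSON sidecars, CSV, and JSON are the interchange
formats); volumetry is slice-wise 2-D counting, faithful to the procedure it
reproduces rather than to a 3-D segmentation ideal.
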