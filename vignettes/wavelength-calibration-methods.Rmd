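---
title: "Physical-model wavelength calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical-model wavelength calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(speccal)
deg <- pi / 180
```

# The problem

A grating spectrometer images each wavelength of the light entering its slit
onto a different column of an array detector.  Every quantitative use of the
instrument — Raman or NIR identification, band splicing, intensity
calibration — starts by assigning a wavelength to each pixel.  The standard
recipe records a reference lamp (neon, krypton, mercury–argon) whose emission
wavelengths are known to sub-picometre accuracy from wavelength-standard
databases, locates the lamp peaks on the detector, and fits a low-order
polynomial `wavelength(pixel)`.  Polynomials interpolate well between
reference lines but extrapolate badly: outside the outermost lines, orders
two and three have nothing to constrain their curvature and the error grows
rapidly.

`speccal` instead fits a closed-form *physical model* of the spectrometer.
The model's extrapolation is constrained by the geometry of the instrument
rather than by polynomial coefficients, so the calibrated axis remains
accurate across the full detector, including bands with no reference lines
at all.

# The dispersion model

Light of wavelength $\lambda$ hitting a grating of effective period $d'$
rotated by $\theta_d$ from its flat position, in a spectrometer with
half-deviation angle $\alpha$, leaves the grating at an angle $\beta$
(measured from the flat-position grating normal) satisfying the rotated
grating equation

$$\frac{n\lambda}{d'} = \sin(\beta - \theta_d) + k\,\sin(-\alpha - \theta_d),$$

where $n$ is the signed diffraction order and $k \in \{+1, -1\}$ selects the
sign with which the incident-angle term enters.  A focusing optic of focal
length $f$ then places the image at detector coordinate
$f \tan(\beta - \alpha)$, which in 1-based pixel units (pitch $T$, detector
centre offset $C$, $N_{pix}$ pixels) reads

$$x = \frac{f}{T} \tan\!\Big(\theta_d + \arcsin\big[\tfrac{n\lambda}{d'} -
k \sin(-\alpha - \theta_d)\big] - \alpha\Big) + \frac{C}{T} +
\frac{N_{pix}+1}{2}.$$

The inverse is closed-form as well (`pixel_to_wavelength()`), and the two
compose to the identity to machine precision — the package's tests hold this
to below $10^{-9}$ nm across every shipped configuration.

## Sign conventions

The literature is inconsistent about how the incident-angle term combines
for the two grating families, and the equation above is sensitive to that
choice.  We fix the convention *empirically*, by requiring each geometry to
image its physical band:

* **Reflection (Czerny–Turner)**, $k = +1$: the band centre obeys the
  textbook formula $\lambda_c = 2 d' \cos\alpha \sin\theta_d$, giving
  realistic grating angles of 6–23 degrees for visible bands on the shipped
  500 mm configurations.
* **Transmission (volume-holographic at 45 degrees)**, $k = -1$: at
  $\theta_d = 0$ the axial wavelength is $2 d' \sin\alpha$ — the symmetric
  Bragg condition — which for 2455 lines/mm puts the modeled band at
  528–617 nm, bracketing the instrument's stated 530–610 nm window.

With the opposite assignment the transmission band would land at an
unphysical ±45 nm and the reflection order $n = -1$ would produce negative
wavelengths, so the convention above is the only one consistent with both
instruments.  `spectrometer_params()` applies it automatically from
`grating_type`; `k` can be overridden for unusual bench layouts.

Note also that for the transmission instrument the "half-deviation" slot
holds the grating's 45-degree tilt with respect to the optical axis — a
slightly different physical reading of $\alpha$ than in the Czerny–Turner
case, but the same symbol in the model.

## The pixel frame

The raw detector-frame coordinate has its origin where the optical axis
crosses the detector; we add the fixed offset $(N_{pix}+1)/2$ so pixels are
1-based with centres at integers, and $C = 0$ places the axial wavelength at
the detector centre.  This makes $C$ directly interpretable as a physical
misalignment of the camera.

## Effective grating period

Vertical displacement of the source along the slit tilts the rays out of the
dispersion plane and is equivalent to shrinking the grating period by
$\cos\gamma$.  Since $d$ and $\gamma$ only ever appear as the product
$d' = d\cos\gamma$, the package models $d'$ alone; the two are not
separately identifiable and storing them separately would only invite
inconsistency.

# The calibration algorithm

Given $N$ reference peaks — sub-pixel positions $x^0_i$ paired with database
wavelengths $\lambda^0_i$ — calibration means finding the parameter set that
best predicts the observed positions, then evaluating the inverse model on
the integer pixel grid.

A brute-force search over all six parameters (`calibrate_bruteforce()`)
defines the problem cleanly but is intractable at useful resolutions, so it
is kept as the reference implementation and cross-checking oracle.  The
production algorithm (`calibrate_physical()`) exploits the model's
structure: $f$, $T$ and $C$ enter only as a scale and shift of the detector
coordinate.  Therefore:

1. brute-force search a 3-D grid over the nonlinear parameters
   $(\alpha, d', \theta_d)$ only;
2. inside each cell, predict positions with nominal $(f_0, T_0, C_0)$ and
   absorb their errors by ordinary least squares of a *first-order*
   polynomial mapping predicted to observed positions;
3. select the cell (and its fitted map) minimizing the summed squared
   position misfit.

The absorption is exact, not approximate: a wrong focal length or camera
offset changes the predicted positions by precisely an affine map, so the
regression recovers it to machine precision.  The tests verify that peaks
generated with $f$ off by 1% and $C$ off by 30 um are calibrated back to
below $10^{-6}$ nm.

For the output axis the package applies the *algebraic inverse* of the
fitted map to the integer pixel grid (observed frame to model frame) before
the inverse model.  Fitting the map in one direction and applying it in the
same direction — which a literal reading of the usual `polyfit`/`polyval`
notation suggests — differs at second order for near-identity maps and
would leave a small systematic residual; the inverse-composition is the
self-consistent choice and is what makes the exact-absorption property
above hold literally.

Step 1 of the procedure (`estimate_initial()`) bootstraps the nominal
parameter set: $f_0$, $T_0$, $d_0$ come from the data sheet, $\alpha_0$ from
a manual measurement, and $(C_0, \theta_0)$ from a 2-D search matching a
single identified peak.

## Numerical choices

* **Misfit in the regression.**  The residual sum of squares is formed from
  explicit residuals, not the textbook shortcut
  $S_{yy} - S_{xy}^2/S_{xx}$, which cancels catastrophically (to a
  $\sim 10^{-10}$ px$^2$ floor) exactly where it matters — near-perfect
  cells — and can then misrank neighbouring cells.
* **Tie-breaking.**  Cells whose misfits agree within $10^{-15}$ relative
  are resolved by distance to the grid centre in normalized coordinates,
  then lexicographically by parameter values.  The selection is therefore a
  pure function of the grid, independent of evaluation order or chunking
  (asserted in the tests).
* **Grid defaults.**  `default_physical_grid()` spans $\alpha_0 \pm 0.5°$
  (step 0.01°), $d'_0 \pm 0.2\%$ (step 0.005%) and $\theta_0 \pm 0.5°$
  (step 0.005°), sized to how well those quantities are known from data
  sheets and manual measurement; a configurable cell budget (default
  $10^7$) guards against accidental explosions.  An optional single
  refinement pass (`refine = TRUE`) re-searches one original step around
  the winning cell at a tenth of the step; since the winning cell is
  contained in the refined grid the misfit can only decrease.  No gradient
  polish replaces the grid: the search stays exhaustive by design, which
  makes it robust to the misfit's nonconvexity and trivially reproducible.
* **Degenerate inputs.**  Fewer than four peaks, fewer than two distinct
  positions, grids missing a physical solution (arcsin out of range on
  every cell) and non-monotone output axes are all hard errors, not
  warnings.  Polynomial calibrations that lose monotonicity across the
  detector (possible for extrapolated cubics) warn and flag the result
  instead, because the evaluation schemes legitimately score such fits.

# Sub-pixel peak localization

The model is only as good as the measured positions, so each detected apex
is refined by least-squares fitting the four-parameter Lorentzian

$$I(x) = \frac{P_1}{(x - P_2)^2 + P_3} + P_4$$

over a window of ±5 px (Levenberg–Marquardt via `minpack.lm`).  Lorentzian
profiles match emission-lamp line shapes convolved with typical instrument
responses well, and direct shape fitting is marginally more accurate than
Fourier upsampling, which this package deliberately does not implement.
Start values come from the apex (centre), window minimum (baseline) and the
half-maximum crossing (width); windows containing saturated pixels are
rejected outright since saturation flattens the apex and biases the centre.
Noiseless model data are recovered to machine precision; under counting
noise at amplitude $10^4$ over baseline $10^2$ the centre lands within
0.05 px in at least 95% of trials (asserted as a property test).

Detected positions are matched to the line list in *wavelength* space — each
position is mapped through the inverse model of the coarse initial parameter
estimate and paired with the nearest line within a tolerance in nm, where
the tolerance has physical meaning.  Matching is one-to-one and
order-preserving; ambiguities are errors, and unmatched positions or lines
are reported rather than dropped.

# Evaluation schemes

Three schemes score a calibration against reference peaks, all computed from
the method's *continuous* map rather than by interpolating the per-pixel
table (which would add a $\sim 10^{-4}$ nm artifact):

* **ALL** — calibrate on all peaks, score all peaks.  The traditional,
  optimistically biased, in-sample number.
* **LOO** — leave-one-out cross-validation; scores accuracy *within* the
  lamp band without in-sample bias.
* **LHO** — calibrate on the left half of the peaks by position, score the
  right half, then swap.  With odd $N$ the left half takes the extra peak
  (a deterministic rule where any choice is defensible).  Both the per-side
  metrics with their average and the pooled union of held-out errors are
  reported, since either aggregation is found in practice.

Metrics are MAE, RMSE and SD (the $N-1$ denominator about the signed mean
error; undefined — reported as `NA`, never zero — for a single error).
Ensembles over $M$ spectra are unweighted means of per-spectrum metrics,
not pooled recomputations.

# The synthetic-data generator

`simulation_spec()` + `render_spectrum()` emulate a recorded reference
spectrum from a configuration and a line list: lines are placed by the
forward model, rendered with the same Lorentzian shape used in fitting
(default width $P_3 = 4$ px², FWHM 4 px, typical of a well-focused lamp
line), on a constant baseline (default 100 counts) with per-line amplitude
(default $10^4$ counts, an exposure just below 16-bit full scale), and
Poisson noise on baseline plus signal.  `render_ensemble()` adds
per-spectrum Gaussian jitter of the grating angle, emulating the practice of
recording many reference spectra with slight grating movements.  Exact
sub-pixel line positions are returned as ground truth, and everything is
deterministic under the mandatory seed.

Matching the rendering shape to the fitting model is deliberate: it
separates algorithm correctness from line-shape mismatch, which can be
studied independently via `shape = "gaussian"`.  What the generator does
*not* emulate — slit-image curvature across detector rows, stray light,
detector nonlinearity, wavelength-dependent line intensities, cosmic-ray
spikes — bounds what passing tests show: they validate the algorithms under
the model's own assumptions, not end-to-end accuracy on any particular
physical instrument.

## Study conditions used in the shipped tests

The test suite and `scripts/acceptance.R` exercise the pipeline at fixed
desk-scale conditions: 16 equally spaced lines on the 600 lines/mm
configuration with 0.02 px position noise for parameter-recovery trials
(50 trials; MAE at the reference lines below 0.005 nm in at least 90%), and
the 12-line synthetic list on the 2455 lines/mm transmission configuration
with 0.05 px position noise — the localization accuracy the Lorentzian
stage itself delivers under counting noise — for the LOO/LHO comparison
(10 noise realizations, ensemble-averaged).  At those conditions the cubic
baseline's leave-half-out MAE exceeds the physical method's by more than a
factor of 5, while the two methods' leave-one-out MAEs agree within a
factor of 3 — the desk-scale analogue of the field observation that
polynomial and physical calibrations are comparable inside the lamp band
but diverge by one to two orders of magnitude outside it.  Search grids in
the tests are kept to a few hundred cells centred on the generating values;
the default grid is two to three orders of magnitude larger and is meant
for real calibrations where the truth is not known to be near a cell.

# A worked example

```{r example}
p <- read_config(system.file("extdata", "config_czerny_turner_600.cfg",
                             package = "speccal"))
lines <- read_linelist(system.file("extdata", "neon_lines_nist_air.csv",
                                   package = "speccal"))

sim <- simulation_spec(p, lines, noise = "poisson", seed = 7)
rec <- render_spectrum(sim)

found <- extract_peaks(rec$spectrum, lines, p, min_prominence = 500)
cal <- calibrate_physical(found$peaks, p,
                          search_grid(
                            alpha = grid_axis(p$alpha, 0.05 * deg, 0.01 * deg),
                            d_eff = grid_axis(p$d_eff, 5e-4 * p$d_eff, 1e-4 * p$d_eff),
                            theta_d = grid_axis(p$theta_d, 0.05 * deg, 0.005 * deg)))
cal
summarize_errors(peak_errors(cal, rec$truth))[c("MAE", "RMSE", "SD")]
```

# Known limitations

* Out-of-plane detector tilt and defocus are not modeled; only the in-plane
  scale/shift family of camera errors is absorbed by the linear map.
* The refractive index of air is not corrected for: line-list wavelengths
  are used exactly as given.  Air-to-vacuum handling belongs in the line
  list, upstream of this package.
* Only a single cropped detector row is consumed; 2-D image distortion
  (slit-image curvature across rows) must be dealt with at acquisition.
* Wavenumber conversion for Raman work is out of scope; the product is a
  wavelength axis.
* Grid search cost grows with the cube of the per-axis resolution; the cell
  budget exists precisely because a naively fine grid is the main practical
  failure mode.
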