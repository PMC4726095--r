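---
title: "Measuring opaque blood flow with X-ray microbubble velocimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring opaque blood flow with X-ray microbubble velocimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpiv)
```

## The measurement problem

Optical velocimetry cannot see blood flowing in deep vessels: tissue is
opaque. X-ray projection imaging can, but it trades the occlusion problem
for three new ones. First, every frame is a line-of-sight integral — all
tracers along the beam path superimpose, so a 2D image of a cylindrical
vessel mixes fast centerline tracers with slow near-wall ones. Second,
static anatomy (bone, organ boundaries, the vessel wall itself) is imaged
on top of the moving tracers, usually with far more contrast than they
have. Third, flux-starved high-speed imaging is noisy, because the image
intensifier works at the edge of its budget.

`xpiv` implements the full measurement chain that turns such image series
into hemodynamic quantities: image restoration, speckle quality metrics,
two-frame cross-correlation velocimetry, and inversion of the
projection-averaged velocity profile. Gas microbubbles (mean diameter
13.3 um in the default configuration) act as the tracer: their
refractive-index step against blood gives them a bright-rim/dark-core
appearance in phase-contrast projection.

## The flow model and its projection

Steady flow of a shear-thinning fluid in a straight circular vessel of
radius $R$ is modeled by the bluntness power law

$$u(r) = V_{max}\left(1 - (r/R)^K\right),$$

where $K \ge 1$ is the bluntness index: $K = 2$ is parabolic Poiseuille
flow, larger $K$ is the blunter, more plug-like profile typical of blood.
The volumetric flow rate is the area integral,
$Q = V_{max}\,\pi R^2\, K/(K+2)$.

A projection image does not measure $u(r)$. At transverse offset
$x = \xi R$ from the vessel axis the beam averages $u$ along the chord
through the cylinder, producing the *amassed* profile
$v(x) = V_{max}\,\alpha(\xi, K)$ with

$$\alpha(\xi, K) = 1 - \frac{1}{\sqrt{1-\xi^2}}
  \int_0^{\sqrt{1-\xi^2}} \left(\xi^2 + \eta^2\right)^{K/2}\, d\eta .$$

Two closed forms anchor the implementation and its tests:
$\alpha(0, K) = K/(K+1)$ and $\alpha(\xi, 2) = \tfrac{2}{3}(1-\xi^2)$.
`alpha_correction()` evaluates the integral by adaptive quadrature
(absolute tolerance $10^{-12}$); a Monte-Carlo chord sampler in the test
suite agrees with it to better than 0.3% over a $(\xi, K)$ grid.
`fit_profile()` inverts the measured transverse profile for
$(V_{max}, K, x_0)$ by bounded nonlinear least squares (Levenberg-
Marquardt via minpack.lm), multi-started from $K \in \{2, 3, 5\}$ with
$K \in [1, 10]$; the free center offset $x_0$ absorbs asymmetric
placement of the vessel in the frame.

```{r alpha}
alpha_correction(0, 2)            # parabolic centerline: 2/3
fit <- fit_profile(seq(-450, 450, 50),
                   amassed_profile(seq(-450, 450, 50), 12.5, 3.31, 500),
                   R = 500)
c(fit$v_max, fit$K)
```

## What a station actually measures

The plain chord mean is only the first approximation to what an
interrogation window reports, and the difference matters once the vessel
is only a couple of hundred pixels across. `fit_profile()` therefore
exposes a forward model of the *measurement operator* with two
refinements, both derived from the imaging geometry rather than fitted:

1. **Finite window extent.** A window spanning rows
   $[x - h, x + h]$ averages stations across $h$; rows are weighted by
   the projected tracer density, which for tracers uniform per unit
   volume is the chord depth $\sqrt{R^2 - x'^2}$. Near the wall this
   weighting leans toward the faster inner rows; ignoring it biases the
   fit blunt (high $K$).
2. **Finite speckle width.** The window cross-correlation is a
   superposition of per-tracer peaks of width $\sigma$ (the standard
   deviation of the speckle autocovariance lobe, measurable from the data
   via `speckle_size()`). Its maximum is the self-consistent weighted
   mean $D = \sum u\,w / \sum w$ with $w = \exp(-(D-u)^2/2\sigma^2)$,
   which sits slightly mode-ward of the chord mean — most visibly at the
   centerline, where the chord spans the full velocity range. The
   correction vanishes as $\sigma$ grows and is solved by a fixed-point
   iteration inside the model.

`run_pipeline()` uses both refinements automatically, passing the window
half-height and the measured speckle width of the restored stack. This is
the same move the field makes when it obtains projection correction
factors by simulating the measurement: the operator is modeled, then
inverted.

## Image restoration

`restore()` chains three stages, in this order:

1. **Flat-field correction** divides out illumination nonuniformity.
   With calibration frames: `(frame - dark)/(flat - dark)`, renormalized
   to preserve the intensity scale. Without them (the usual situation in
   vivo) each frame is divided by a heavily smoothed copy (Gaussian,
   sigma = rows/8) of the temporal mean.
2. **Background elimination** subtracts the pixelwise mean of
   `background_window` frames (default 100). Subtraction deliberately
   collapses the frame mean to the residual tracer-signal scale (the
   residual is shifted so its 1% quantile sits at zero): that collapse is
   what raises speckle contrast $C = \sigma_I / \mu_I$, since the static
   anatomy contributes mean but no tracer signal. A `rebase = "mean"`
   mode restores the original mean instead for users who need
   mean-preserving stages.
3. **Band-pass filtering** keeps spatial wavelengths in
   `[4, 64]` px (half-power at the edges, Gaussian transfer functions,
   DC restored). The lower edge removes intensifier noise; the upper
   removes residual large-scale structure. The ~7 px bubble speckle sits
   comfortably inside the band.

Calibration comes before statistics, denoising last. The ordering and the
cutoffs are configuration, logged with every run; the per-stage speckle
contrast is recorded in a restoration log so the before/after effect is
auditable.

For a static scene the background stack may use every available frame,
and longer is better: moving tracers average into faint streaks whose
amplitude falls as 1/window, and slow near-wall tracers are otherwise
partially subtracted with the background, which skews chord statistics
toward the fast side. The pipeline's synthetic studies use the full
sequence for this reason; with real, slowly deforming anatomy a shorter
window (the 100-frame default) is the right compromise.

## Quality metrics

Three numbers summarize measurability, computed exactly as the chain uses
them: speckle contrast $C$ (population sd over mean of an ROI), speckle
size (FWHM of the ensemble-averaged normalized autocovariance, computed
per frame by Wiener-Khinchin with per-frame mean subtraction, averaged,
then normalized to unit zero lag), and the reliability product
$SR = P_c \times C$, where $P_c$ is the peak value of the zero-normalized
cross-correlation map. A vector is treated as reliable when
$P_c \ge 0.5$; the sweep utility (`measurability_sweep()`) reports the
largest displacement setting whose mean $P_c$ still clears that line.

## The PIV engine

`compute_field()` tiles the frame pair with windows (default
32 x 64 px, long axis along the flow, 50% overlap), correlates each pair
of windows by zero-normalized cross-correlation (FFT-based, numerically
identical to the direct double-loop definition to $10^{-10}$), refines
the peak with a per-axis 3-point Gaussian fit (parabolic fallback on
non-positive neighbors), and validates vectors by the $P_c$ threshold
plus a normalized-median outlier test (3 x 3 neighborhood, threshold 2,
noise floor 0.1 px). `ensemble_mean()` averages instantaneous fields
per grid point over valid vectors (default 200 pairs; points valid in
fewer than 25% of fields are dropped), and `to_physical()` closes the
units: px/frame times pitch times frame rate.

$P_c$ is defined as the maximum correlation coefficient, not a
peak-to-second-peak ratio; the definition is isolated in
`correlate_windows()` so the alternative reading can be swapped in one
place. Peak-location ties break deterministically (smallest lag
magnitude, then row-major).

## The synthetic scene generator

Every stage above is testable because `generate_sequence()` renders
ground-truth-known sequences: bubbles uniform per unit volume in a
cylinder (uniform in $r^2$), advected by the bluntness law, drawn as
difference-of-Gaussians rim/core templates (rim sigma 0.35 d, core
sigma 0.20 d) at subpixel positions, equally sharp at every depth
(projection imaging has no focal plane), summed over overlaps, composed
with a static tissue-like background and a multiplicative illumination
ramp, plus Gaussian sensor noise. No wave-optics propagation is
simulated: the template is a phenomenological stand-in for the
phase-contrast appearance.

Defaults emulate a 1024 x 1024 px, 1000 fps acquisition at
1.8994 um/px with 13.3 um bubbles (lognormal diameters, CV 0.15; only
the mean is physically anchored). Two generator choices deserve
explanation:

* **Open-boundary recycling.** Bubbles leaving the axial domain
  re-enter at the inflow with a fresh azimuth and a radius drawn from the
  flux-weighted density $p(r) \propto r\,u(r)$ — the unique re-injection
  law under which the uniform concentration is exactly stationary (a
  radial class loses members at a rate proportional to its count times
  its speed, so the influx must be flux-weighted). This mirrors a
  continuously seeded pipe and keeps long sequences statistically fresh.
* **Dense seeding.** The default density is ~48 bubbles per 32 x 64
  window. In the dense regime the window correlation is a compound peak
  whose maximum estimates the weighted chord mean — the quantity the
  amassed-profile inversion assumes. Sparse seeding instead makes every
  vector a winner-takes-all draw among a few bubbles (the largest bubble
  usually wins), which is both noisier and biased. Design studies during
  development showed parameter recovery degrading markedly below ~10
  bubbles per window.

What the generator does *not* emulate — Fresnel fringes, polychromatic
spectra, red blood cell texture, vessel wall motion, pulsatility — bounds
what passing tests show: they validate the measurement chain against the
stated flow and image model, not against every property of beamline data.

## Study sizes and numerical choices

The synthetic studies in the test suite use 256 x 256 px scenes
(vessel radius 200 um), 400-frame sequences, 200-pair ensembles, and
$V_{max} = 4.5$ mm/s (about 2.4 px/frame at the centerline, inside the
quarter-window search rule): large enough that parameter recovery is
limited by the method rather than by statistics, small enough to run
routinely. At these conditions the pipeline recovers $K^* \in \{2, 3.31,
6\}$ within 15% and $V_{max}$ within 10% in at least 9 of 10 seeded
repeats. The restoration-efficacy fixture deliberately degrades the
scene (static structure ~1.5x the bubble amplitude, noise ~1.8x) until
raw correlation locks to the stationary background peak — reproducing the
failure mode restoration exists to fix.

Other numerical choices: quadrature tolerances $10^{-10}$ relative for
$\alpha$; the fixed-point peak model iterates at most 12 times to
$10^{-10}$; the subpixel offset is clamped to $(-1, 1)$ px; zero-variance
windows yield invalid vectors rather than errors; $\xi \ge 1$ returns
$\alpha = 0$ by continuity; all RNG flows through per-scene seeds so a
`(config, seed)` pair reproduces stacks, fields and fits byte for byte.

## Buoyancy correction

Gas bubbles rise. The Stokes terminal velocity
$v_t = \Delta\rho\, g\, d^2 / (18\mu)$ for the default parameters
(13.3 um diameter, blood at 1060 kg/m^3 and 2.4 mPa s, CO2 at
1.8 kg/m^3) is about 0.043 mm/s — under 0.5% of a 10 mm/s flow —
and `buoyancy_correct()` subtracts it from the gravity-aligned component
of a physical-unit field. The fluid viscosity and density behind that
number are configuration, not constants of nature; they are exposed as
arguments.

## Known limitations

* The inversion assumes a steady, axisymmetric, straight vessel;
  branching, curvature and pulsatility violate it in ways the free
  center offset only partially absorbs.
* The correlation-peak station model assumes a Gaussian speckle
  autocovariance lobe and equal per-tracer energy; strongly polydisperse
  tracers weight the fast/slow mix by bubble size.
* Wall shear stress is out of scope: near-wall vectors are too sparse
  and too smeared for a defensible gradient.
* Background elimination partially cancels tracers that move less than
  one speckle width over the stacking window; near-wall velocities are
  the casualty. Longer windows help only for static anatomy.
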