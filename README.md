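# xpiv — X-ray particle image velocimetry for opaque blood flow

Blood flowing in deep vessels cannot be measured optically: tissue is
opaque. X-ray projection imaging with gas microbubble tracers can see it,
at the price of three complications this package exists to handle:

* **Everything superimposes.** A projection frame integrates along the
  beam, so static anatomy is imaged on top of the moving tracers —
  usually with more contrast than the tracers have. `xpiv` restores such
  frames by flat-field correction, background elimination (stacking
  consecutive frames), and spatial-frequency band-pass filtering.
* **Measurability must be quantified.** Speckle contrast
  `C = sd/mean`, the speckle size (FWHM of the normalized intensity
  autocovariance), the relative correlation peak height `P_c`, and their
  product `SR = P_c * C` quantify whether a velocity measurement can be
  trusted; `P_c >= 0.5` is the reliability criterion used throughout.
* **Projection averages the profile.** A cylindrical flow
  `u(r) = V_max (1 - (r/R)^K)` (bluntness index `K`; `K = 2` is
  parabolic, blood is blunter) is seen in projection as the *amassed*
  profile `v(x) = V_max * alpha(|x|/R, K)`, where `alpha` is the chord
  average of `u/V_max`:

      alpha(xi, K) = 1 - (1 - xi^2)^(-1/2) * Int_0^sqrt(1-xi^2) (xi^2 + eta^2)^(K/2) d eta

  with `alpha(0, K) = K/(K+1)`. `xpiv` computes `alpha` by quadrature,
  fits the amassed model to measured profiles by bounded nonlinear least
  squares, corrects for microbubble buoyancy via the Stokes terminal
  velocity `v_t = d rho g d^2 / 18 mu`, and reports
  `Q = V_max pi R^2 K/(K+2)` in mL/min.

The velocity measurement itself is classical two-frame PIV:
zero-normalized cross-correlation over interrogation windows (default
32 x 64 px, 50% overlap), 3-point Gaussian subpixel refinement,
`P_c`/median-test validation, ensemble averaging over (by default) 200
frame pairs, unit conversion via pixel pitch and frame rate.

A seeded synthetic scene generator renders ground-truth-known microbubble
sequences — cylinder flow, rim/core bubble templates, static tissue-like
background, illumination gradient, sensor noise — so the entire chain is
testable without beamline data. It is first-class, tested code, not a
fixture.

Intended users: experimental fluid dynamicists and biomedical imaging
groups doing X-ray (or other projection) velocimetry of opaque flows, and
anyone needing a reproducible desk-scale testbed for projection-PIV
algorithms.

## Worked example

Simulate a vessel (radius 200 um, `V_max` 4.5 mm/s, `K* = 3.31`,
1000 fps at 1.8994 um/px), restore, measure, and invert:

```r
library(xpiv)

scfg <- scene_config(frame_shape = c(256, 256), vessel_radius = 200,
                     v_max = 4.5, bluntness = 3.31, seed = 1)
rc <- run_config(scene = scfg,
                 restore = restoration_config(background_window = 120),
                 piv = piv_config(window_size = c(32, 64),
                                  max_displacement = c(5, 6)),
                 n_frames = 120, n_pairs = 60)
run <- run_pipeline(rc)
print(run)
#> <xpiv_run>
#> <xpiv_profile_fit> v_max = 4.546 mm/s, K = 3.196, R = 200.0 um, x0 = 1.3 um
#>   residual RMS = 0.0620 mm/s, Q = 0.0211 mL/min, n = 15 samples
#>   mean P_c = 0.927, valid vectors = 98%, C raw -> restored: 0.0971 -> 0.3346
```

Reading the output: the fitted maximum velocity (4.546 mm/s) and
bluntness (3.20) recover the ground truth (4.5, 3.31) to within about
1% and 4%; `Q` is the flow rate implied by the fitted profile; the mean
relative peak height 0.93 is far above the 0.5 reliability line; and
restoration raised speckle contrast from 0.097 to 0.335 — the
enhancement that makes the correlation usable at all. The Stokes rise
velocity of a 13.3 um CO2 bubble in blood-like fluid,
`stokes_terminal_velocity(13.3)`, is 0.0425 mm/s, under 0.5% of typical
aortic velocities, and is subtracted when a `stokes` block is configured.

Longer runs tighten the numbers: with 400 frames and 200-pair ensembles
the recovery of `K` is typically within a few percent (see
`tests/testthat/test-acceptance.R`).

A thin command-line front-end wraps the same functions
(`inst/cli/xpiv.R`; verbs `simulate`, `preprocess`, `metrics`, `piv`,
`profile`, `pipeline`, `sweep`), reading YAML configurations and writing
TIFF/CSV/JSON with the seed and a config hash embedded.

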