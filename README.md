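# spindlequant

Quantification of mitotic spindle architecture from multi-channel
fluorescence microscopy, with a ground-truth synthetic spindle generator
for validating every measurement stage.

## The scientific problem

The mitotic spindle of human cells is built from distinct microtubule
bundle classes: **k-fibers** that attach kinetochores to the spindle poles,
antiparallel **bridging fibers** that laterally link the two sister
k-fibers, and single **astral microtubules** radiating from the poles.
Because individual microtubules cannot be counted directly in light
microscopy, bundle composition is inferred ratiometrically: with an
electron-tomography calibration of *n*<sub>k</sub> = 12.6 microtubules per
k-fiber, the microtubule number of any other bundle follows from
background-subtracted tubulin intensities as

    n_x = I_x · n_k / I_k

Around this estimator the package implements the full analysis toolbox
used to characterize spindle organization and mitotic fidelity:

- **Fiber quantification** — square-ROI and line-profile intensity
  measurement schemes, background rules per imaging modality (10 empty
  areas for STED, 2 for confocal), bridging-fiber detection
  (signal strictly above background), and depletion bookkeeping
  (percent reductions, remaining and nucleation-pathway-dependent counts).
- **Kinetochore geometry** — 3D interkinetochore distances and distances
  to the pole-to-pole axis via the Pythagorean decomposition
  c = √(a² + b²), with the axial term scaled by the 0.81 refractive-index
  correction for oil objectives; sister-axis tilt; inner/outer spindle
  region classification; spindle length, width and plate diameter.
- **End-on view** — re-slicing a side-view z-stack along the spindle axis
  by the axis permutation I′(i·px, j·px, k·zd) = I(k·zd, i·px, j·px) with
  axial rescaling, sum projections, automated bundle counting, and
  diameter intensity profiles.
- **Bundle shape** — least-squares circle fits (algebraic seed + geometric
  Gauss–Newton refinement) giving radius of curvature, and contour lengths
  of traced bundles.
- **Dynamics** — poleward flux from photoactivation-mark-to-pole distance
  series, anaphase A/B speeds from linear fits, and anaphase-onset
  detection from interkinetochore distance series.
- **Segregation errors** — classification of misaligned, lagging and other
  kinetochore pairs from trajectories, missegregation outcomes, and
  per-cell error censuses.
- **PRC1 overlaps** — overlap length as the base of the PRC1 intensity
  peak, total PRC1 intensity, and overlap-to-spindle-length ratios.

A synthetic spindle generator (`make_spindle_model`, `render`,
`make_anaphase_timelapse`, `make_photoactivation_series`) plants known
geometry, photometry, kinetics and error labels, renders them through an
anisotropic-PSF + Poisson/Gaussian noise forward model, and exposes the
ground truth — so every estimator above is tested against known answers.

## Worked example

Simulate a STED calibration scene (k-fibers with 12.6 microtubules, a
bridging fiber with 3.8, astral microtubules with 1), render it with
realistic noise, and measure it back with the square-ROI protocol:

```r
library(spindlequant)

op    <- optics_params("sted")              # 20 nm px, 0.3 um z step
scene <- make_calibration_scene(seed = 8, bridging = TRUE)
stack <- render(scene, op, seed = 8, channels = "tubulin")
meas  <- measure_spindle_fibers(stack, scene, op, seed = 8)

meas$pairs
#>   pair_id      I_b      I_k      n_b bridging_detected
#> 1       1 1.985342 6.431438 3.889536              TRUE
head(meas$astral$n_a)
#> 1.133 1.413 0.660 0.957
```

The bridging fiber planted with 3.8 microtubules is recovered as
n_b ≈ 3.89 from the intensity ratio, and the single-microtubule astral
fibers average n_a ≈ 1 (individual fibers scatter with photon noise; the
calibration criterion uses the mean over ≥ 90 fibers). Depletion
bookkeeping from summary counts:

```r
depletion_summary(
  data.frame(fiber_class = c("bridging", "k_fiber"), n_mt = c(3.8, 12.6)),
  data.frame(fiber_class = c("bridging", "k_fiber"), n_mt = c(1.2, 9.6)))
#>   fiber_class n_control n_remaining percent_reduction n_augmin
#> 1    bridging       3.8         1.2              68.4      2.6
#> 2     k_fiber      12.6         9.6              23.8      3.0
```

i.e. a 68% / 24% intensity reduction leaves 1.2 of 3.8 bridging and 9.6 of
12.6 k-fiber microtubules, attributing 2.6 and 3.0 microtubules to the
depleted nucleation pathway.

A thin command-line dispatcher over the pipeline functions is installed at
`system.file("cli", "spindlequant.R", package = "spindlequant")`.

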