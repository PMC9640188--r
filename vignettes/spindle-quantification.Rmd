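---
title: "Quantifying mitotic spindle architecture: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic spindle architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlequant)
```

# Scope

`spindlequant` re-implements, as tested and reusable code, the measurement
operations used to quantify mitotic spindle architecture in fluorescence
microscopy: ratiometric microtubule counting, 3D kinetochore geometry with
axial correction, end-on re-slicing and bundle counting, bundle-shape circle
fits, photoactivation flux and anaphase kinetics, segregation-error
classification, and PRC1 overlap metrics. Because raw images of the original
experiments are not available, the package pairs each measurement with a
synthetic spindle generator that plants known ground truth and renders it
through a realistic imaging forward model; the tests and the acceptance
script quantify how well each estimator recovers what was planted.

# The ratiometric counting model

Light microscopy cannot resolve individual microtubules inside a bundle, but
tubulin fluorescence is proportional to polymer mass. With a reference bundle
class of known composition — k-fibers with $n_k = 12.6$ microtubules, from
electron tomography of RPE1 spindles — any bundle's microtubule number
follows from background-subtracted intensities:

$$n_x = \frac{I_x \, n_k}{I_k}.$$

Two measurement schemes feed this estimator:

* **Square ROIs** (`measure_square_roi`, `background_square`,
  `corrected_fiber_intensity`): block means on a single z-plane. ROI sides
  default to 25 px on STED images (20 nm pixels) and 5 px on confocal images
  (83 nm pixels), i.e. roughly 0.4–0.5 µm. The background rule differs by
  modality: 10 randomly placed empty areas inside the spindle for STED,
  2 areas just above and below the bridging fiber for confocal, and the
  empty area between the two astral microtubules for astral measurements.
  Strict mode enforces these counts.
* **Line profiles** (`line_profile_method`): intensities along a segmented
  line following the two sister k-fibers and their bridging fiber. The
  minimum of a parallel midzone profile is the background; the bridge center
  is the minimum of the subtracted contour profile; $I_b$ is the mean in a
  window around the center and $I_{bk}$ the mean of two flanking windows
  1.5 µm away, with $I_k = I_{bk} - I_b$.

The published wording "the area 500 nm around the center" is ambiguous
between a total width of 500 nm and a half-width of 500 nm. We read it as a
*total* width (±250 nm), the narrower and more conservative interpretation,
and expose it as `window_halfwidth` so either reading can be used.

Bridging-fiber *detection* uses the strict rule: a fiber is present when its
background-corrected intensity is strictly positive ($I_b > 0$; a value of
exactly 0 counts as absent). Since photon noise makes this rule stochastic
near the boundary, an optional z-score mode ($I_b > k\sigma_{bcg}$) is
provided but is not the default.

Depletion bookkeeping (`depletion_summary`, `depletion_bookkeeping`) is pure
arithmetic on class means: percent reduction
$100(1 - \bar n_{depl}/\bar n_{ctrl})$, remaining count, and the difference
attributed to the depleted nucleation pathway. The default simulation preset
(`apply_depletion`) reproduces the canonical bookkeeping: bridging fibers
3.8 → 1.2 microtubules, k-fibers 12.6 → 9.6, and 41% of pairs left with no
bridging fiber.

# Kinetochore geometry and the axial correction

Distances are computed in scaled coordinates
$(x\,\mathrm{px}, y\,\mathrm{px}, z\text{-plane})\mapsto
(x p, y p, z \cdot \Delta z \cdot 0.81)$, where $p$ is the pixel size,
$\Delta z$ the stage z-step, and 0.81 the axial scaling that corrects stage
distances for the refractive-index mismatch between aqueous sample and
immersion oil. The distance of a pair to the spindle axis is decomposed as
$c = \sqrt{a^2 + b^2}$ with $a$ the in-plane distance to the projected axis
and $b$ the corrected plane offset from the central z-plane; for the
horizontally lying spindles this analysis assumes (the protocol pre-rotates
stacks so the spindle axis is horizontal), $c$ equals the true 3D
point-to-line distance, which the tests verify against a vector-algebra
oracle. The "central z-plane" is not defined in the source protocol; we take
the plane of the pole-axis midpoint.

Region classification ties break toward "outer" in both rules (metaphase:
$c$ equal to the cell mean; anaphase: normalized distance equal to 0.5). The
anaphase rule states the boundary explicitly; we adopt the same convention
for metaphase for consistency.

## Sub-voxel localization

Manual clicking of kinetochore centers is replaced by model-based
localization. Sister separations of ~1 µm are below three axial PSF sigma,
so the two puncta overlap and independent centroids are biased toward each
other; an intensity-weighted centroid also suffers truncation bias of
~0.02 µm at the box edges. `localize_pair` therefore fits, by least squares,
a joint two-Gaussian model (PSF-shaped puncta with free centers and
amplitudes over a constant background) in a box enclosing both annotations.
On noiseless rendered pairs this recovers planted positions to well below
0.01 voxel; the residual bias of the full pipeline on noisy data is assessed
by the recovery tests. `refine_centroid` remains available for isolated
puncta.

# End-on view

`rotate_to_end_on` implements the axis permutation
$I'(i\,p, j\,p, k\,zd) = I(k\,zd, i\,p, j\,p)$: each output plane is a y–z
cross-section at one x position, with the axial coordinate rescaled by 0.81
and resampled to the in-plane pixel pitch (linear interpolation by default;
nearest preserves total intensity exactly in the isotropic permutation
case). Bundle counting on the 10-central-slice sum projection was manual in
the source protocol; the package's operationalization is light Gaussian
smoothing, strict 8-neighborhood maxima, merging below a 0.3 µm minimum
separation, and a 10% prominence floor. The default smoothing is
anisotropic — σ 0.10 µm across rows (y) and 0.25 µm along columns (the
resampled axial direction) — because the axial PSF (σ ≈ 0.35 µm) elongates
each bundle's footprint along that axis and isotropic light smoothing lets
photon noise split one elongated blob into several maxima. The defaults were
validated against planted bundle counts (28 bundles recovered within ±1
averaged over seeds).

# Bundle shape

`fit_circle` seeds an algebraic (Kasa) fit and refines it with Gauss–Newton
iterations on the geometric objective $\sum_i (r_i - R)^2$; the original
analysis scripts do not state which objective they used, so both are
available and the geometric fit is the default (it is the unbiased choice
for partial arcs). 3D traces are first projected onto their best-fit plane,
since traces were made on rotated 2D images. Collinear points return an
infinite radius flagged as a line, distinct from failure; collinearity is
detected from the second singular value of the centered coordinates.
`contour_length` is the cumulative point-to-point distance.

# Dynamics

The photoactivation mark-to-pole distance blurs both channels with σ = 2 px,
profiles them along a 10 px wide pole-to-pole line, and takes the distance
between the mark peak and the nearer tubulin (pole) peak; peaks are refined
by parabolic interpolation around the discrete argmax. Rates are ordinary
least-squares slopes converted to µm/min, with approach speeds (flux,
anaphase A) reported positive and separation (anaphase B) positive.

"Gradually increasing" (anaphase onset) is operationalized as the first run
of 3 consecutive frame-to-frame increases whose cumulative rise is at least
0.1 µm; onset is the last frame before that run. Both parameters are
exposed, as the original criterion was the analyst's eye. The rule is
invariant to adding a constant to the series, and a series with no
qualifying run signals "no onset" rather than guessing.

# Segregation errors

The three-way taxonomy is applied to trajectories: *misaligned* pairs have
both sisters outside the metaphase-plate slab 30 s before onset (nearest
acquired frame); *lagging* pairs show a stretched punctum — elongation
(major/minor axis ratio) above 1.5, the package's reading of "visibly
stretched" — in the central spindle during anaphase; *other* covers pairs
that never separate and central non-stretched stragglers. Precedence is
misaligned > lagging > other. Two operationalizations are this package's
choices where the protocol was visual: the plate slab is the median ± a
robust spread (2.5 MAD, floored at 0.8 µm) of kinetochore axial positions at
the look-back frame, and "central part of the spindle" is the middle third
of the pole-to-pole span. Missegregation is scored from final pole
proximity; exactly equidistant endpoints are unresolved (NA), not guessed.

# PRC1 overlaps

The overlap length is the base of the PRC1 intensity peak along a
pole-to-pole contour. "Base" is undefined in the source description; the
package defines it as the contiguous interval around the peak where the
background-subtracted intensity exceeds a fraction (default 10%) of the peak
height, with threshold crossings located by linear interpolation between
samples. This makes the measure exactly computable for canonical shapes —
a Gaussian of width σ at fraction $f$ gives $2\sigma\sqrt{2\ln(1/f)}$, a
triangle of half-width $w$ gives $2w(1-f)$ — and those closed forms pin the
semantics in the tests. The measure is monotonically non-increasing in the
base fraction. Total PRC1 intensity follows the integrated-density formula
(polygon sum minus area × background mean), using a point-in-polygon test.

# The synthetic generator: what it emulates, and what it does not

`make_spindle_model` plants poles, kinetochore pairs in a prolate shell,
k-fiber arcs (circular, sagging away from the axis), bridging arcs joining
sister k-fiber ends, astral fibers, and per-class microtubule counts
(defaults 12.6 / 3.8 / 1.0). `render` deposits line-integrated intensity —
`mt_count × unit_brightness` per µm — onto the voxel grid by trilinear
splatting, convolves with a separable anisotropic Gaussian PSF, places true
z at plane index $z/(0.81\,\Delta z)$ so the downstream 0.81 correction
recovers true axial distances, and adds background, Poisson shot noise and
Gaussian read noise.

Fixed study conditions (chosen once; they are the conditions under which all
recovery results hold):

| Parameter | Confocal | STED | Why |
|---|---|---|---|
| pixel size | 0.083 µm | 0.020 µm | acquisition settings of the two modalities |
| z step | 0.5 µm | 0.3 µm | acquisition settings |
| PSF σ_xy | 0.11 µm | 0.035 µm | typical for the modality (not measured in the source) |
| PSF σ_z | 0.35 µm | 0.35 µm | axial resolution is confocal-limited in both |
| axial scale | 0.81 | 0.81 | oil-objective refractive-index correction |
| background | 10 a.u. | 5 a.u. | moderate-SNR regime |
| unit brightness | 2000 a.u./MT/µm | same | sets single-microtubule SNR: a 1-MT STED ROI sits clearly above shot noise, as usable raw data must |
| noise | Poisson (gain 1) + read σ 1 | same | standard detector statistics; the source states none |

The source data report no raw-image SNR, so the noise level is a package
choice stated here and in the config, not inferred from the source.
Time-lapse defaults follow the acquisition protocols: 10 s frame interval
for photoactivation, 30 s for anaphase imaging. Anaphase A/B and flux speed
defaults (1 µm/min) are typical human-cell values; every planted speed is an
explicit argument, and the kinetics tests sweep several.

The calibration scene (`make_calibration_scene`) is planar and uses exactly
two astral microtubules per pole at ±13° with mild k-fiber sag. This mirrors
the measurement protocol (single z-plane ROIs on rotated images with fibers
locally parallel to the axis, background between the two astral fibers) and
reflects a property of axis-aligned square ROIs: their effective path length
grows as fibers tilt away from the image axes, so the ratio estimator is
calibrated for near-parallel fiber geometry, in simulation as in practice.

What the generator does **not** emulate: microtubule polymerization dynamics
or forces, spindle-shape variability beyond parameterized arcs, depth- or
wavelength-dependent PSF changes, bleaching, drift, chromatic offsets, or
multipolar spindles. Passing recovery tests therefore demonstrates that the
estimators are correct and unbiased under the stated imaging model — not
that they are robust to every artifact of real data.

# Numerical choices and degenerate inputs

* Convolution kernels are discrete Gaussians truncated at 3σ and
  renormalized at the array edges, so blurring conserves total intensity.
* Fiber centerlines are resampled at half-pixel steps before splatting.
* A flat contour profile yields $I_k = 0$ with a degenerate-center warning;
  a flat-bottomed dip takes the center of its argmin plateau.
* Coincident sisters, coincident poles, and sub-3-point circle fits raise
  errors; collinear circle fits return radius ∞, flagged, not an error.
* The overlap peak below background returns length 0 with a warning.
* `detect_onset` returns NA with a warning when no run qualifies.
* Derived seeds stay below $2^{31}$; every generator is a pure function of
  its arguments including the seed.

# Problem sizes

The validation suite runs at desk scale, sized so the whole suite finishes
in well under a minute of compute per module: calibration recovery uses 30
STED scenes (≥ 90 astral fibers), bundle counting 10 seeds of 28-bundle
phantoms, interkinetochore recovery 110–120 rendered pairs, tilt recovery 78
pairs, and kinetics sweeps 3 planted speeds × 6 seeds. These sizes match the
per-condition sample sizes of the original measurements where those are
stated (e.g. tilt on 78 pairs, distance on ~120 pairs).

# Known limitations

* ROI placement is annotation-driven (or ground-truth-driven in
  simulation); the package does not segment or trace fibers from pixels.
* The square-ROI estimator inherits the orientation dependence of
  axis-aligned ROIs; measurements of strongly tilted fibers are biased high
  unless the image (or ROI) is rotated, exactly as with the interactive
  protocol it reproduces.
* The axis-distance decomposition assumes a horizontally lying spindle;
  tilted spindles should be rotated first (the end-on module's transform
  assumes the same).
* Overlap length depends on the base-fraction convention; comparisons
  across datasets must hold it fixed.
* The classifier's plate-slab and middle-third rules are explicit
  operationalizations of visual judgments; their parameters are exposed and
  should be reported alongside results.
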