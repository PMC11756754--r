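---
title: "Models and measurement procedures in capsmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement procedures in capsmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsmorph)
```

capsmorph quantifies bright-field time-lapse z-stacks of cell assemblies
growing inside hollow alginate capsules, the kind of data produced by
compact microscopes living inside cell-culture incubators. This vignette
explains the models behind each stage, the defaults and why they were
chosen, what the synthetic scenes do and do not emulate, and the known
limitations.

## Instrument model

Three plan-achromat objectives are supported. The stored calibrations are
the instrument's working values: pixel equivalence (sample-plane size of
one camera pixel) of 1.08, 0.432 and 0.216 um for 4X, 10X and 20X, fields
of view of 6 x 4, 2.3 x 1.6 and 1.15 x 0.8 mm², and numerical apertures
0.10, 0.25 and 0.40. The diffraction limit follows the Rayleigh criterion
$d = 0.61\,\lambda/\mathrm{NA}$ at the 0.625 um LED peak, giving 3.8, 1.52
and 0.95 um — in every mode the pixel equivalence is below the optical
resolution, so detection is diffraction-limited. The stored fields of view
are treated as authoritative and the sensor arithmetic
(5472 x 3648 pixels of 2.4 um) is only checked against them as a soft
consistency test (3% tolerance), because the published values are rounded
to two significant figures.

The NA of the 10X objective is set to 0.25, the standard plan-achromat
value; it reproduces the 1.52 um mid-range resolution exactly. No tube-lens
or parfocal arithmetic is modelled: the pixel equivalences are calibration
constants, not derived quantities.

## Focus-stage kinematics

The focus drive is a hobby servo turning the stage micrometer through a
36:25 gear pair. With a 500 um/revolution micrometer pitch — the unique
value consistent with the two design anchors of a 10 um minimum step (5
degrees, the smallest rotation the servo executes reliably) and 360 um full
travel (180 degrees) — travel is
`angle x (36/25) x 500 / 360` um. Stack plans are quantized to 10 um
multiples and bounded by the full travel.

The stochastic simulator emulates the drive's measured behaviour: each
5-degree quantum of a commanded step fails to execute with probability
`lock_prob` (default 0.15) and Gaussian jitter (sd 0.1 um) is added per
step. Lock-ups are *positional* by default — tied to the step index, i.e.
to reproducible sticking angles of the servo travel — because that is the
only reading consistent with the hardware's signature of 80–90% step
accuracy alongside ~99% run-to-run precision: were lock-ups independent
across runs, the run-to-run spread of a 10 um step would be several
micrometres and precision would drop to ~70%. An `independent` mode is
available for comparison. Accuracy is defined as the mean achieved/commanded
ratio and precision as one minus the mean relative run-to-run standard
deviation, both in percent.

## Synthetic scenes

Each generator renders ground-truthed bright-field frames so that every
measurement stage can be validated by parameter recovery. The forward model
is multiplicative transmission: cell layers transmit 0.45 of the incident
intensity, cyst lumens 0.9, alginate walls 0.8 (fixed, arbitrary contrast
choices — no measurement stage depends on their exact values, only on the
sign and approximate strength of the transitions). Defocus is a Gaussian
blur of width $\sigma(z) = \sigma_0 + c\,|z - z_\mathrm{object}|$ with
$\sigma_0 = 1$ px and $c = 0.05$ px/um; a physical point-spread function is
deliberately out of scope. Detector noise is additive Gaussian with sd 2%
of the incident intensity, and frames are quantized to integer counts like
the 16-bit camera. All randomness derives from the scene seed; rendering a
given plane at a given time is fully deterministic.

**Spherical scenes** place capsules (outer diameter 450 um, core 300 um,
each varied uniformly by ±10%) on a grid, with one lumenized cyst per
capsule at a random depth in the 0–240 um working range. The growth law
keeps the shell volume exactly exponential,
$V(t) = V_0\,2^{t/\mathrm{PDT}}$ with PDT 15 h by default, while the layer
thickness follows a piecewise-linear function of lumen radius (slopes 0.1
then 0.3 beyond a 40 um critical radius); the lumen radius trajectory is
obtained by numerically inverting the volume law under that thickness
constraint. This partition reconciles the two observables the analysis
targets — exponential volume growth and a slope change in
thickness-versus-radius — without asserting anything about how real cysts
partition their growth.

**Tubular scenes** render a hollow tube (outer diameter 260 um, core 190
um) containing one spherocylindrical cyst drawn as a stadium footprint with
separate tip and lateral layer thicknesses. Length and width grow
exponentially in time with rates chosen to reach +90% and +10% over an 18 h
window — the functional form is a generator choice; only the endpoint gains
are anchored.

**Yeast scenes** place an absorbing spherical aggregate in each capsule;
transmitted intensity follows the Beer–Lambert law
$I = I_0 e^{-\mu d}$ with $d$ the chord length through the aggregate.
Aggregate volume doubles every 330 min (per-capsule rates varied by 5% to
emulate biological spread) after a 4 h lag. The scene default absorption is
$\mu = 0.01\,\mu m^{-1}$: aggregates grow to ~70 um radius, and the centre
optical depth $\mu \cdot 2R$ must stay below the logarithmic clip floor
(see below) for depth inversion to remain informative; all headline yeast
quantities are normalized volumes, in which $\mu$ cancels anyway.

What the scenes do **not** emulate: cell-scale texture, scattering and
refraction at the capsule interfaces, illumination drift, stage drift, free
yeast darkening the background over time, and multi-cyst capsules. Passing
recovery tests on these scenes therefore demonstrates the correctness of
the measurement machinery under the stated geometry and noise — not
robustness to every artefact of real acquisitions.

## Focus selection

The per-region sharpness score is normalized gradient energy: mean squared
gradient magnitude divided by squared mean intensity. The normalization
makes selection invariant to illumination rescaling. The best plane is the
per-object argmax over the stack, ties breaking toward the lowest z. On
single-capsule scenes with 80 um stacks the selected plane lands within one
stack step of the true object depth in well over 95% of cases.

## Cyst morphometry

Capsule detection thresholds pixels darker than 87.5% of the background
median, labels connected components, and keeps ring-shaped components whose
outer radius lies in 180–280 um; the ring centroid is the capsule centre
and the near-edge radial quantiles give the outer and core radii.

Cyst profiling casts 70 equally spaced rays (angle-uniform) from the
intensity-weighted centroid of the dark cell layer. Each radial intensity
profile is sampled at half-pixel steps by bilinear interpolation, smoothed
with a Gaussian of sigma 2 px, and differentiated: the lumen-to-layer
boundary is the strongest negative gradient extremum and the layer-to-medium
boundary the strongest positive extremum beyond it, both refined to
sub-sample precision by parabolic interpolation — for a blurred step edge
the gradient extremum sits exactly at the edge, which is why recovery on
noiseless scenes is within a quarter pixel. The centroid is re-estimated
once from the mid-layer points and the rays re-cast. Rays without a
credible band, or whose outer boundary runs off the profiling range, are
excluded and counted. Solid pre-lumen clusters (dark at the centroid) are
flagged and reported with zero lumen radius and the equivalent radius of
the dark area as thickness.

The shell volume uses the spatially averaged radius and thickness,
$V = \tfrac{4}{3}\pi\left((\bar r + \bar t)^3 - \bar r^3\right)$ — the
concentric-sphere form, not a per-ray integral.

Tracking profiles each capsule's cyst on its best-focus plane at every
timepoint. A known, accepted bias: when the cyst equator falls between two
stack planes, the visible annulus is a chord cross-section and the measured
radius underestimates the true one by up to
$r(1 - \sqrt{1 - (\Delta z/r)^2})$. With 40 um stack steps the residual
doubling-time bias is about −0.2 h on a 15 h truth, an order of magnitude
inside the acceptance window; no model-based correction is applied.

## Tube morphometry

The tube axis is the averaged principal direction of the two wall-band
pixel clouds, fitted per band — a joint fit over both bands is biased by
frame clipping. Wall offsets come from near-edge quantiles of the signed
normal distances; their gap is the core diameter. The cyst is segmented at
72% of background (the half-amplitude level of the layer/medium edge, so
the contour sits on the true boundary), hole-filled, and measured by
projecting pixel coordinates on the axis and its normal: length L, width D,
area A, and the projection volume $V = A \times D$ — the stated
solid-of-revolution approximation, uncorrected for end caps. Tip and
lateral thicknesses are dark-band widths along rays cast from the centroid
along and across the axis. Colliding or docking cysts are not handled;
scenes and analysis assume one confined cyst.

## Beer–Lambert volumetry

Incident intensity is the per-frame median of pixels outside all capsules
(robust to gradual darkening; a background sd above 5% of the median raises
an inhomogeneity flag). Depth inversion is
$d = -\ln(\mathrm{clip}(I/I_0, e^{-6}, 1))/\mu$; pixels at the clip floor
have lost depth information and their fraction is reported so analyses can
gate on it (the tests require < 1%). Volumes integrate $d$ times the pixel
area over the aggregate mask within the capsule core. The mask applies a
5 um depth floor: without it, zero-mean detector noise rectifies into a
spurious positive volume over the large clear core area (the expected
one-sided excess is about $0.4\,\sigma_I/(\mu I_0)$ um per pixel, which
integrates to a volume offset of order 10% of a 50 um aggregate) and biases
the doubling-time fit; the floor discards only the thin rim where the chord
is shorter than 5 um, a negligible volume. Normalized series are invariant
to both $\mu$ and global intensity rescaling.

The exponential fit window starts at a configurable `t_fit_start` (default
4 h, the end of the lag phase); it is a parameter rather than a constant
because the appropriate start depends on when imaging begins relative to
encapsulation.

## Growth kinetics

Doubling times come from ordinary least squares of log volume on time:
exact on noiseless exponential data, stable under multiplicative noise, and
free of starting-value issues; a nonlinear refinement on the original scale
is available behind `refine_nls = TRUE` for strongly heteroscedastic data.
PDT is $\ln 2 / k$ with a delta-method standard error. Since the ± spread
reported alongside published doubling times may be either a standard
deviation or a standard error over replicates, both are computable from the
per-object fits returned.

The thickness-versus-radius relation is fitted by continuous two-segment
least squares: the breakpoint is found by exhaustive search over interior
observed radii (which on noiseless piecewise data returns the true grid
point exactly) followed by golden-section refinement of the residual sum of
squares between the neighbouring grid points. A two-parameter F-test
against the single-line fit at $\alpha = 0.05$ gates the slope change;
linear data fall back to a single slope with the breakpoint flagged
undefined, preventing spurious critical radii.

## Problem sizes and numerical choices

The validation suite renders single-capsule frames of ~500 px at the 4X
pixel equivalence, five 33-timepoint spherical time-lapses with 7-plane
stacks for doubling-time recovery, one 49-timepoint 6-capsule yeast scene,
and one 19-timepoint tubular scene — sizes chosen so a full run of the
acceptance analysis completes in a few minutes on one core while keeping
every estimate's sampling error far inside its tolerance. Ray profiles are
sampled at half-pixel steps; profile smoothing sigma is 2 px; gradient
thresholds are 1% of background per um, an order of magnitude below true
edge slopes. Degenerate inputs (constant regions, empty masks, all-equal
radii, zero reference values) return zero scores, warnings or errors as
documented rather than propagating NaN.

## Known limitations

* Measurement operators are tuned for the transmission-mode contrast
  polarity (dark cell layers on bright background) and assume roughly
  circular/tubular geometry; collapsed or confluent cysts are out of scope.
* The cross-section bias discussed above applies to any finite stack step;
  callers who need unbiased radii at coarse stacks should fit the
  plane-to-plane radius profile instead.
* Beer–Lambert volumetry assumes a spatially uniform absorption
  coefficient; real aggregates densify as they grow.
* The stage simulator reproduces summary statistics of the drive, not its
  mechanics; backlash on direction reversal is ignored because stacks are
  acquired monotonically.
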