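# capsmorph

Quantitative analysis of bright-field time-lapse z-stacks of cell
assemblies growing inside hollow alginate capsules — the data produced by
compact bright-field microscopes that live inside cell-culture incubators
and watch encapsulated samples for days without moving them.

The package is written for experimentalists running such instruments on
three sample classes, and for anyone who wants a fully synthetic,
ground-truthed testbed for this kind of morphometry:

* **Spherical capsules with epithelial cysts** (e.g. human induced
  pluripotent stem cells): a closed single-cell layer of thickness *t*
  around a fluid-filled lumen of radius *r*. Both are measured at 70
  positions around the cyst by radial intensity profiling, and the shell
  volume follows the concentric-sphere form
  *V* = (4/3)π((*r* + *t*)³ − *r*³). Exponential fits of *V*(t) yield the
  population doubling time PDT = ln 2 / *k*, and a continuous two-segment
  regression locates the critical lumen radius (~40 μm) beyond which the
  layer thickens faster with radius.
* **Tubular capsules with confined cylindrical cysts**: length *L*, width
  *D* and projected area *A* measured against the tube axis, with the
  projection volume *V* = *A* × *D* and separate tip/lateral layer
  thicknesses — capturing strongly anisotropic growth (order +90% axial
  vs +10% radial over 18 h).
* **Yeast aggregates**: per-pixel Beer–Lambert inversion
  *d* = −ln(*I*/*I*₀)/μ of single-plane transmitted intensity turns each
  pixel into an elementary volume; integrated volumes give doubling times
  (~330 min after a ~4 h lag).

Around these measurements the package provides the instrument optics model
(Rayleigh limits, objective calibrations tying pixels to micrometres), a
stochastic simulator of the servo-plus-gear focus drive (36:25 gear, 10 μm
minimum step over 360 μm travel, with its characteristic 80–90% accuracy /
~99% precision signature), per-object focus-plane selection on z-stacks,
and a synthetic scene renderer that generates ground-truthed TIFF
time-lapses of all three sample classes so that every stage is validated
by parameter recovery.

All measurement functions take and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Render a spherical-cyst time-lapse (one capsule, true PDT 15 h, 90-minute
cadence, 40-μm z-stacks over the 240-μm working range), track the cyst,
and fit its growth:

```r
library(capsmorph)

scene <- spherical_scene(pdt = 15, seed = 42)
tl <- make_timelapse(scene, duration_h = 24, cadence_h = 1.5,
                     stack_plan = plan_stack(240, 40))$timelapse
series <- track_cysts(tl)
head(dplyr::select(series, cyst_id, time, z_um, r_um, t_um, v_um3), 4)
#> # A tibble: 4 × 6
#>   cyst_id  time  z_um  r_um  t_um   v_um3
#>     <int> <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1       1   0     160  29.7  12.1 197104.
#> 2       1   1.5   160  30.7  12.3 211316.
#> 3       1   3     160  31.9  12.3 226324.
#> 4       1   4.5   160  33.0  12.4 242177.

fit <- fit_exponential(series$time, series$v_um3)
fit
#> <growth_fit>
#>   rate k  : 0.04658 /h (se 9.96e-05)
#>   PDT     : 14.88 h (se 0.0318)
#>   V0      : 1.9688e+05
#>   n, window: 17 points over [0, 24] h
```

The tracker found the cyst in focus at z = 160 μm, measured a lumen radius
growing from 29.7 μm and a layer thickening from 12.1 μm (the generator's
true initial geometry is 30 and 12 μm), and the fitted doubling time of
14.88 h recovers the configured 15 h to within one percent. `autoplot(fit)`
draws the series with the fitted exponential; `tidy(fit)` returns the
estimates as a tibble.

The same pattern runs the other two pipelines: `track_tube()` +
`relative_series()` for confined cysts, and `track_yeast()` +
`yeast_doubling_times()` for encapsulated yeast.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts/capsmorph-cli", package = "capsmorph"))')
$CLI simulate --kind spherical --outdir data/run1 --seed 7 --duration 24
$CLI track-cyst --indir data/run1 --outdir results/run1
$CLI fit --csv results/run1/cyst_series.csv --outdir results/run1
```

Time-lapses are plain multi-page 16-bit TIFFs (`t0000.tif`, ...) with a
YAML calibration sidecar; results are CSV plus a JSON report carrying the
configuration hash and seeds, and identical configurations reproduce
byte-identical outputs.

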