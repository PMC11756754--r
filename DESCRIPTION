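Package: capsmorph
Title: Morphometry and Growth Kinetics of Encapsulated Cell Assemblies from
    Bright-Field Time-Lapse Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bright-field time-lapse z-stacks of cell
    assemblies growing inside hollow alginate capsules, as acquired by compact
    incubator microscopes. Provides the instrument optics model (Rayleigh
    resolution, objective calibrations), a servo-driven focus-stage simulator,
    a ground-truthed synthetic scene renderer for spherical cysts, tubular
    cysts and yeast aggregates, focus-plane selection, 70-ray radial cyst
    morphometry with concentric-shell volumes, tubular-cyst length/width/area
    measures, Beer-Lambert per-pixel optical-depth volumetry, and growth-curve
    fitting (exponential doubling times and continuous two-segment breakpoint
    regression). All measurement functions return tibbles; fitted objects have
    tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    digest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    segmented,
    optparse,
    withr
Config/testthat/edition: 3
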