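Package: echotex
Title: Echotexture Analysis of B-Mode Ultrasonograms with Trait-Correlation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: First-order echotexture analysis of B-mode ultrasound images of
    skeletal muscle: greyscale conversion, byte-scale (histogram stretching)
    normalization, circular spot-meter placement, and computation of mean
    pixel intensity (MPI) and pixel heterogeneity (MPH) per image and per
    subject-by-scanning-plane. Includes the downstream statistical pipeline
    used in livestock meat-quality phenotyping (one-way ANOVA with Tukey HSD
    and compact letter displays, two-way ANOVA with LSD post hoc, and a
    Pearson correlation screen of echotexture variables against
    physicochemical and sensory meat traits, with regression equations and
    Guilford strength labels), plus a synthetic Rayleigh-speckle image and
    trait-table generator so the full chain can be exercised and calibrated
    without proprietary scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
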