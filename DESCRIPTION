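Package: condensorheo
Title: FCS-Calibrated Imaging, Particle-Tracking Microrheology and
    Centrosome Cohesion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the abundance and material state of centrosomal
    protein assemblies in live-cell fluorescence microscopy.  Provides a
    multiple-tau autocorrelator and diffusion-model fitting for
    fluorescence correlation spectroscopy (FCS), confocal-volume
    calibration from dye measurements, conversion of confocal images to
    absolute molar concentration and per-structure copy numbers,
    single-particle-tracking mean-squared-displacement microrheology with
    Stokes-Einstein viscosity estimation, normalization and rate fitting
    of fluorescence recovery after photobleaching (FRAP), and
    distance-threshold scoring of centrosome cohesion.  Synthetic-data
    generators for intensity traces, bead tracks, calibration-cell images
    and FRAP series allow the whole pipeline to be exercised and validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
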