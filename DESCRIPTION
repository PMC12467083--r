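Package: palpmap
Title: Stiffness Mapping for Fiber Bragg Grating Palpation Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for an endoscopic palpation probe that senses
    tissue stiffness with four fiber Bragg gratings (FBGs) embedded in an elastic
    dome. Provides sub-resolution Bragg-peak localization by Gaussian fitting of
    four-peak reflection spectra, per-channel wavelength-shift tracking between
    contact and pressed acquisitions, a summed-absolute-shift relative-stiffness
    statistic with per-session min-max normalization, interpolated 2D stiffness
    heat maps with stiff-region detection, and a forward simulator of palpation
    sessions over tissue phantoms with embedded rigid inclusions so the full
    pipeline can be exercised and validated without probe hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    interp,
    igraph,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
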