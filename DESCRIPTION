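Package: aquapolar
Title: Aquaphotomics of Polarized Near-Infrared Interactance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for aquaphotomics of short-wave near-infrared
    (800-1050 nm) interactance spectra of fruit measured under polarized and
    unpolarized light, with and without skin. Implements absorbance conversion,
    standard normal variate and Savitzky-Golay second-derivative preprocessing,
    principal components analysis, water matrix coordinate (WAMACS) band
    assignment and activated-wavelength selection, soluble-solids-content
    grouping and difference spectra, and aquagram (relative standard normal
    variate) radar charts. A seeded forward simulator generates fruit phantoms
    and instrument-like spectra for the four measurement configurations with
    known injected water-band effects, so the whole chain is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
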