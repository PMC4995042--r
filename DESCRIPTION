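Package: ccocta
Title: Simulation and Grading of Choriocapillaris OCT Angiography Under Drusen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation pipeline comparing how a shorter-wavelength
    (840 nm) spectral-domain and a longer-wavelength (1050 nm) swept-source
    OCT angiography (OCTA) device visualize the choriocapillaris underneath
    drusen. Builds a layered digital macular phantom with dome-shaped drusen
    and a choriocapillaris flow layer, simulates repeated-B-scan OCT amplitude
    volumes with Beer-Lambert attenuation, sensitivity roll-off, speckle and
    a noise floor, computes pairwise amplitude-decorrelation angiography with
    OCT-signal thresholding, projects Bruch's-membrane-referenced en face
    choriocapillaris slabs, and grades per-druse signal loss as ambiguous,
    unambiguous, or false-positive flow impairment, with cohort aggregation
    and interreader agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
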