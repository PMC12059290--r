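Package: resp4dct
Title: Breathing Surrogate Simulation and Evaluation for Breathing-Adapted 4DCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for respiratory surrogate signals in
    intelligent, breathing-adapted four-dimensional computed tomography (4DCT)
    sequence scanning. Generates synthetic sinusoidal and cos^6 breathing curves with
    controllable irregularity, emulates table-mounted, ceiling-mounted and reference
    optical surrogate systems including couch-step patch-propagation artifacts,
    implements the retrospective table-motion correction for surface-camera curves,
    simulates intelligent X-ray trigger selection with a 20 s training period and
    reference-breathing-curve construction, places amplitude- and phase-based
    reconstruction bins, evaluates image quality through the inferior-superior centre
    of mass of a rendered spherical tumor phantom, and quantifies and estimates
    inter-system latencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
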