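Package: tavisim
Title: Access-Route Feasibility Simulation for Transcatheter Aortic Valve
    Implantation in Hemodialysis Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based simulation of transcatheter aortic valve implantation
    (TAVI) access-route feasibility from per-vessel computed-tomography
    measurements. Provides six-level ordinal grading of vascular calcification
    degree and range, a decision engine classifying the transfemoral,
    transcervical, trans-subclavian and direct-aortic routes against an
    expandable-sheath diameter criterion (instructions-for-use and
    fully-expanded modes) with a transapical fallback, sheath-to-femoral and
    sheath-to-iliofemoral artery ratio metrics with published
    vascular-complication cut-offs, a seeded synthetic generator emulating the
    calcification structure of a hemodialysis cohort, and cohort-level
    reporting with count-and-percentage tables and unadjusted odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
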