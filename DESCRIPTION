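Package: pcbrtm
Title: Reactive Transport Modelling of PCBs in Bioaugmented Sediment Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compartmental reactive transport modelling of polychlorinated
    biphenyl (PCB) congeners in sealed sediment microcosms, shaken or
    nonshaken, with first-order aerobic biodegradation and a bioavailability
    factor describing sorption to suspended degrader cells. Includes two-site
    fast/slow sediment desorption, intraparticle radial diffusion (method of
    lines with an analytic-series oracle), two-film air-water exchange,
    passive-sampler (polyurethane foam and solid-phase microextraction)
    uptake sub-models with a cell-fouling observation model, a measurement
    reduction pipeline (limit-of-quantification censoring, surrogate
    recovery correction, group statistics), seeded multi-start parameter
    calibration, and a synthetic-experiment generator so the full
    simulate-reduce-compare-calibrate analysis runs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
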