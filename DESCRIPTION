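Package: dragtag
Title: Quantifying the Effect of External Tag Drag on Swimming Eels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the energetic burden of externally attached
    telemetry tags on anguilliform swimmers. Implements spherical drag-dummy
    sizing and empirical drag-curve calibration, swim-tunnel respirometry
    analysis (oxygen-uptake slopes, the exponential metabolic model, standard
    metabolic rate, optimal swimming speed and minimum cost of transport),
    Brett critical swimming speed with solid-blocking correction, undulatory
    swimming kinematics (tail-beat frequency, amplitudes, body-wave speed,
    Strouhal number), and a through-origin quadratic model mapping added drag
    to percent impairment of energetic endpoints, with attachment-site
    adjustment. A seeded synthetic-cohort generator produces complete virtual
    swim-trial datasets so every pipeline stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
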