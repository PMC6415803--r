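Package: corolla
Title: Parametric Flower Morphospace and Instrumented Pollination Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring a theoretical flower morphospace and for
    analysing instrumented hawkmoth foraging trials. Generates parametric
    corolla geometry (a four-parameter generating curve revolved into a
    watertight, 3D-printable STL shell), simulates ground-truthed foraging
    trials (per-morph visit and nectar-emptying records; synchronized
    accelerometer, infrared-beam and video channels), tracks the pollinator
    by reference-frame subtraction, detects flower contacts as total-
    acceleration peaks, and estimates plant and pollinator fitness surfaces
    (visitation frequency, foraging success rate, energy-gain rate, contacts
    per visit) together with their factorial ANOVA, t-test and regression
    analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
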