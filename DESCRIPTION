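Package: pfevolve
Title: Predictive Models of Stress-Response Gene Circuit Evolution in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the short-term experimental evolution of a synthetic
    positive-feedback (PF) stress-response gene circuit integrated in the
    budding yeast genome. Provides cellular and population fitness landscapes
    over inducer (doxycycline) / antibiotic (zeocin) / expression space built
    on a zeocin-binding steady-state submodel, a two-state (Off/On)
    growth-and-switching model of the bistable circuit, a lumped ODE model of
    ancestral and knockout/tweaking/generic mutant classes, and a detailed
    stochastic allele-level evolution simulator with serial-dilution
    bottlenecks, gradual drug uptake and a pre-existing-mutation variant.
    Also includes allele-frequency time-course reconstruction from mixed
    Sanger/whole-genome calls with linkage resolution, clone-phenotyping
    statistics, and synthetic-data generators emulating every measurement
    layer the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
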