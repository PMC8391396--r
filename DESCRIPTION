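Package: thermoflux
Title: Thermodynamic Flux Analysis and Comparative Flux Profiling of
    Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds thermodynamically constrained flux models (TFA) from a
    stoichiometric network, a table of standard transformed formation
    energies and metabolite concentration bounds, and solves FBA,
    parsimonious FBA and parsimonious thermodynamic flux variability
    analysis (pTFVA) as mixed-integer linear programs.  Fits exponential
    growth and specific exchange rates from time-course cell counts and
    medium concentrations with a robust soft-L1 loss, propagates
    measurement error into flux bounds, and implements a normalization
    cascade (growth-rate division, per-reaction feature scaling, division
    by a paired control) with a dual-bound relative-difference statistic
    and per-subsystem summaries for comparing drug-resistant and
    drug-sensitive model instances.  Includes production-envelope sweeps
    of oxygen against fatty-acid influx and a seeded generator of toy
    networks, thermodynamic tables and four-condition time-course
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr
Config/testthat/edition: 3
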