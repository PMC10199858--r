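Package: ImmunoPatlak
Title: Kinetic Quantification and Cohort Simulation for Zirconium-89
    Immuno-PET Dose-Escalation Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of zirconium-89 labelled
    monoclonal-antibody PET studies with antibody mass-dose escalation:
    decay correction, percent injected activity, standardized uptake
    values, organ- and tumor-to-plasma ratios, bi-exponential plasma
    input-function fitting, Patlak graphical analysis of irreversible
    uptake (Ki), receptor-occupancy saturation metrics, and the group
    statistics used to compare mass-dose arms. A seeded synthetic-cohort
    generator reproduces the design of a six-patient anti-LAG-3 antibody
    imaging study (three mass doses, two imaging cycles, saturable
    target-specific uptake, immune-infiltration heterogeneity) with full
    ground truth retained for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports: stats, utils, jsonlite, yaml, minpack.lm
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
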