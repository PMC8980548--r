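Package: hdmprof
Title: Molecular Sensitization Profiling of House Dust Mite IgE Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for component-resolved analysis of multiplex house dust
    mite (HDM) specific-IgE panels. Reads patient-level sIgE tables for the
    eleven Dermatophagoides pteronyssinus and D. farinae molecules measured
    by multiplex assays, binarizes levels at the conventional 0.35 kU/L
    sensitization threshold, computes per-molecule prevalence summaries
    stratified by age group and region, enumerates exact co-sensitization
    profiles, and classifies the one or two priority sensitizing molecules
    per region using an absolute-maximum share rule with a 5-percentage-point
    margin and a one-sample upper-tail Student's t confirmation step. A
    seeded synthetic-cohort generator (Gaussian-copula latent-threshold
    binary model with log-normal positive sIgE levels) provides realistic
    correlated test data, and a pipeline driver ties the stages into one
    reproducible run with a machine-readable manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
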