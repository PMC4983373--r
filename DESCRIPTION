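Package: fabsec
Title: Quantification of Free Therapeutic Antibody and Immune Complexes
    by Size-Exclusion Chromatography with Fluorescent Fab Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a size-exclusion chromatography (SEC) assay that
    quantifies free therapeutic antibody and anti-drug-antibody (ADA) immune
    complexes in serum using a fluorescently labelled monovalent Fab detection
    reagent. Implements the closed-form tight-binding (quadratic) mass-action
    equilibrium and its nonlinear least-squares K_D fit, simulation and global
    fitting of 1:1 Langmuir surface-plasmon-resonance sensorgrams with
    stoichiometry arithmetic from response units and molecular masses,
    rendering and window-based integration of fluorescence chromatograms with
    a percentage-area signal-to-noise statistic and limit-of-detection search,
    immune-complex size-class profiling across ADA titrations, a
    supernatant/pellet densitometry mass balance for precipitated complexes,
    and multi-dose timecourse analysis of study samples. Seeded synthetic-data
    generators emulate every input the pipeline consumes so that all analyses
    are exercisable and testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    pracma,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
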