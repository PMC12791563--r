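Package: spaceclock
Title: Longitudinal Epigenetic Clock Analysis for Small Spaceflight Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal DNA methylation aging-clock data in
    very small repeated-measures cohorts, such as astronaut missions. Computes
    epigenetic age difference (EAD), epigenetic age acceleration (EAA) and
    intrinsic epigenetic age acceleration (IEAA) across a registry of linear
    epigenetic clocks; tests within-subject timepoint changes with paired
    Wilcoxon signed-rank and sign-flip permutation tests over the clock panel;
    fits crossed random-intercept mixed models across subjects and clocks;
    attributes the EAA-IEAA gap to immune cell types by dominance analysis;
    applies arbitrary linear clocks to beta matrices and estimates 12-cell
    immune composition by non-negative reference-based deconvolution; and ships
    a fully seeded synthetic-cohort generator with known ground truth for
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
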