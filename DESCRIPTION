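Package: longdesign
Title: Evaluation of Follow-Up Designs for Longitudinal MRI Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how the number of follow-up visits, the
    interval between visits and the study duration affect the conclusions of
    longitudinal MRI studies of white-matter bundles. The package simulates
    dense longitudinal tractometry-style datasets with participant-specific
    intercepts and slopes, subsamples them into candidate follow-up designs,
    estimates per-participant change with linear mixed models, compares
    designs with repeated-measures ANOVA (Mauchly sphericity test,
    Greenhouse-Geisser correction, Tukey post-hoc tests, Benjamini-Hochberg
    FDR), computes correlation-adjusted sample sizes from noncentral-F power
    for one-group within-subjects ANOVA, and audits which MRI-clinical
    Spearman associations are preserved, lost, gained or sign-flipped
    relative to the full design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
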