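Package: tswp
Title: Analysis of Task Switching with Preview Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing behavioural logs from task switching with
    preview (TSWP) experiments, in which two classification tasks alternate in
    a predictable AAABBB sequence and the upcoming task's stimulus may be
    visible in advance. Implements the full analysis pipeline: trial-log
    ingestion and validation, response-time exclusion cascades and participant
    quality control, fast-switch scoring against a single-task quantile
    threshold with a compensatory-prolongation correction, fast-switch rates
    (FSR) per participant and condition, classification of participants into
    serial, semi-overlapping and overlapping processing modes, and the robust
    statistics the design calls for (20% trimmed means, heteroscedastic
    between-by-within trimmed-means ANOVA with adjusted-F degrees of freedom,
    AKP and KMS robust effect sizes, and classical repeated-measures ANOVA
    with Greenhouse-Geisser correction). A synthetic-cohort generator with
    fixed-duration blocks and mode-dependent preview use makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
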