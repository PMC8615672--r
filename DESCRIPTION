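Package: actirhythms
Title: Actigraphy Sleep and Rest-Activity Rhythm Analysis for Cross-Sectional Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing wrist-actigraphy recordings of sleep and
    circadian rest-activity rhythms in cross-sectional cohorts. Provides epoch-level
    reading, quality control and day alignment; Actiware-style weighted-moving-average
    sleep scoring with total sleep time, sleep efficiency and wake after sleep onset;
    template-matching activity onset/offset detection and single-component cosinor
    fitting (MESOR, amplitude, acrophase); the van Someren non-parametric circadian
    rhythm statistics (interdaily stability, intradaily variability, L5, M10, relative
    amplitude); periodogram-based circadian-band relative power; a permutation-ANOVA
    (Freedman-Lane) and hierarchical linear-model protocol with Holm correction; and a
    seeded synthetic-actogram cohort generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
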