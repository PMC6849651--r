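Package: bcrpanel
Title: Prognostic Biomarker Discovery for Biochemical Recurrence from
    NanoString Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a NanoString nCounter prognostic
    biomarker discovery workflow for biochemical recurrence (BCR) after
    radical prostatectomy. Provides lane-level quality control and
    three-step count normalization (positive-control scaling, background
    subtraction, housekeeping scaling), SAM-style permutation differential
    expression for tumor-only counts and paired tumor/normal ratios,
    Storey-Tibshirani q-values with expected-false-positive accounting,
    per-probe cutoff selection and binarization, greedy OR-rule multi-gene
    panel construction, qRT-PCR delta-Ct ERG scoring, and cross-platform
    (count, qRT-PCR, IHC) ERG-call concordance. A seeded synthetic-cohort
    generator emulates the study design (21 BCR / 42 non-BCR patients,
    paired tumor and normal samples, a 151-probe CodeSet with housekeeping
    and spike-in control probes) so the whole pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
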