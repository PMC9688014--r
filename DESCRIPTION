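Package: rinstab
Title: Replicative Instability Characterization in Multi-Omics Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize replicative instability (RIN) in tumor
    cohorts from gene-level multi-omics tables. Implements MYBL2
    quartile stratification with Kaplan-Meier/log-rank survival comparison,
    essentiality-weighted DNA-repair pathway expression (WE) scores, a
    replication-stress (RS) expression score, intragenic mutational position
    scores (MPS), alteration-frequency profiling of replication-stress
    sensitive (ERFS/MiDAS) genomic sites, rule-based attribution of fusion
    junctions to error-prone repair pathways, and metastatic dissemination
    and brain-metastasis risk summaries. Ships a seeded synthetic-cohort
    generator with configurable planted effects so every stage can be
    exercised and calibrated without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    survival,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
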