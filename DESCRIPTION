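Package: capcogs
Title: Enhancer-Gene Scoring and GWAS Gene Prioritisation from Promoter Capture Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links distal regulatory elements to genes from Promoter Capture Hi-C
    (PCHi-C) data and prioritises GWAS effector genes through promoter contacts.
    Implements Activity-by-Captured-Contact (ABCC) enhancer-gene scoring on
    CHiCAGO-normalised interaction counts with Brownian-floor contact imputation;
    multiCOGS, a fine-mapping-aware Bayesian gene prioritisation score combining
    multiple credible sets per linkage-disequilibrium block; summary-statistic
    z-score imputation and single-causal-variant posteriors; a transplantation
    permutation test for epigenomic enrichment of collapsed promoter-interacting
    regions; and an alternative-promoter contact-sharing classifier. Ships seeded
    synthetic-data generators with planted ground truth for every input the
    toolkit consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    IRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
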