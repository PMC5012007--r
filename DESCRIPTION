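Package: adaptomics
Title: Integrative Differential Phosphoproteomics of Drug-Adaptation States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering signaling alterations shared between early
    (drug-persistent) and late (fully resistant) adaptation states of
    kinase-inhibitor-treated cancer cells from label-free quantitative
    (phospho-) proteomic and matched transcriptomic profiles. Implements
    per-feature differential statistics (pooled-variance t, one-way ANOVA)
    with fold-change and FDR filter presets, direction-of-change concordance
    with Fisher's exact test, permutation Kolmogorov-Smirnov signature
    enrichment, GSEA-style running-sum enrichment with normalized enrichment
    scores for kinase-substrate and transcription-factor target sets, a
    case/control specificity filter, rank-rank hypergeometric overlap maps,
    pairwise signature correlation with hierarchical clustering, and a
    combined perturbation score that ranks candidate shared targets across
    contrasts. A fully specified synthetic-data generator emulates the
    parental/persistent/resistant experimental design with planted effect
    programs so every stage is testable end to end.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
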