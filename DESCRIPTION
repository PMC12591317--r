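Package: phosdiff
Title: Genotype-Specific Differential Proteomics and Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for label-free quantitative proteomic and
    phosphoproteomic cohort analysis across genotype groups (EML4-ALK, EGFR,
    KRAS, triple wild-type lung adenocarcinoma). Implements MaxQuant-style
    intensity-table ingestion, group-wise presence filtering, hybrid missing
    value imputation (sample 5-percentile / feature kNN for proteomes;
    condition-specific and tail-based down-shifted normal for phosphosites),
    median scaling, an adaptive parametric/nonparametric test cascade
    (Shapiro-Wilk and Levene gated ANOVA, Welch-ANOVA, Kruskal-Wallis and
    pairwise Student, Welch, Wilcoxon tests) with per-feature
    Benjamini-Hochberg false discovery rate control, alteration-specificity
    classification, kinase-substrate enrichment analysis (KSEA z-scores), and
    Cohen's d preranked gene set enrichment analysis. Ships a synthetic cohort
    generator with intensity-dependent (MNAR) dropout for fully offline,
    ground-truth-aware testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
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
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
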