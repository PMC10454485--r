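Package: grcmeth
Title: Cell-Type-Resolved and Genotype-Risk-Corrected Whole-Blood Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of whole-blood
    DNA methylation in case/control designs with heavy immune-cell admixture.
    Implements reference-based estimation of six immune-cell fractions from
    beta-value matrices, per-CpG logistic EWAS with and without correction for
    known genetic risk (HLA tag-SNP haplotype dosage and a polygenic risk
    score), differentially methylated region calling by Fisher, Stouffer and
    harmonic-mean combination, per-cell-type interaction models attributing
    differential methylation to individual cell types, a causal inference test
    (CIT) for genotype -> methylation -> disease mediation, a genotype-risk-
    corrected methylation score compared against genetic scores by ROC/AUC,
    cis-window methQTL ANOVA, and a seeded synthetic-cohort generator that
    emulates the statistical structure of such studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
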