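Package: gwaskit
Title: Genome-Wide Association and Genomic Prediction Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless, scriptable toolkit for genome-wide association
    studies (GWAS) and genomic prediction on biallelic SNP data. Reads and
    writes VCF and PLINK 1 binary (BED/BIM/FAM) genotypes with minor-allele
    frequency and missing-rate filtering, builds genomic relationship
    (kinship) matrices, and fits a spectral-decomposition linear mixed
    model for association mapping alongside per-SNP linear regression.
    Machine-learning association scans (random forest, gradient-boosted
    trees, ridge regression) aggregate per-marker feature importances over
    repeated randomized train/test splits; genomic prediction supports
    GBLUP and the same learners under a seeded hold-out protocol evaluated
    with Pearson correlation and Bland-Altman agreement. Includes Manhattan,
    QQ, kinship-heatmap, PCA and summary visualizations, a Balding-Nichols
    genotype/phenotype simulator with designed causal markers, and a
    command-line interface chaining the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    ranger,
    xgboost,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
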