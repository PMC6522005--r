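Package: taxafun
Title: Comparing Microbiome Form and Function Between Host Genotype Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the taxonomic composition ("form") and
    predicted functional gene content ("function") of 16S rRNA microbiome
    surveys between host genotype groups. Implements feature-table ingest
    (QIIME-classic TSV and classic-BIOM JSON) with singleton filtering and
    rarefaction; alpha/beta diversity with permutation statistics (ANOSIM,
    Mantel, Monte-Carlo two-sample tests); core-microbiota extraction with
    exact prevalence decay curves and AUC contrasts; per-group Spearman
    co-occurrence network inference with exact small-n permutation p-values
    and topology metrics; a simplified negative-binomial Wald test for
    differential abundance; a nearest-sequenced-taxon functional predictor
    with weighted NSTI scoring; and a ground-truth synthetic community
    generator for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    picante,
    phyloseq,
    igraph,
    biomformat,
    jsonlite,
    Matrix,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
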