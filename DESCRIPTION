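Package: senescore
Title: Senescence Signature Scoring for Tumour Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores the degree of latent senescence signalling in bulk gene
    expression data using directional multi-marker signatures: a DNA
    damage-associated senescence (DAS) signature and a modified secretory
    senescence (mSS) signature.  Expression is median-normalized across
    arrays and each sample receives the percentage of expressed signature
    genes whose relative expression lies in the pro-senescence direction.
    Downstream stages screen compound growth-inhibition (GI50) panels for
    linear dependence on senescence score, predict broad compound target
    classes from open-formula 2D molecular descriptors with a decision
    tree and quantify activity-class fold enrichment, correlate
    within-group score rankings, cluster samples on the secretory
    signature with a Spearman correlation distance, and compare survival
    of the resulting groups by Kaplan-Meier, log-rank and age/sex-adjusted
    Cox models.  A synthetic-data module generates expression matrices,
    GI50 panels, survival records and small molecules with known planted
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    rpart,
    igraph,
    ChemmineR
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
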