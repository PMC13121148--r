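Package: comorbnet
Title: Ising-Style Comorbidity Network Inference and Differential Omics
    Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted disease-comorbidity networks from binary
    patient-by-diagnosis matrices. Pairwise coupling strengths are
    estimated as pointwise mutual information under a maximum-likelihood
    co-occurrence model, transformed into a weighted network, and
    summarised by strength, expected influence, betweenness and closeness
    centralities; disease modules are delineated by coupling-threshold
    connected components and nodes classified into core, hub and
    peripheral tiers. Network stability is assessed across cohort splits
    via Fisher-z correlation intervals and rank consistency. A companion
    omics arm screens differential proteins and metabolites by fold
    change, paired or unpaired tests, Benjamini-Hochberg FDR and VIP
    scores from an orthogonal projections to latent structures
    discriminant analysis (OPLS-DA) with cross-validation and permutation
    testing. Gibbs samplers for binary Markov random fields and
    planted-module and log-normal omics generators provide fully
    synthetic, seed-reproducible test cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
biocViews: Network, GraphAndNetwork, Proteomics, Metabolomics,
    DifferentialExpression, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
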