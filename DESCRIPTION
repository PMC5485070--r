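Package: stresshap
Title: Kinship-Based Analysis of Multi-Stress Responses in Arabidopsis
    Accession Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantitative genetics of stress
    responses in panels of inbred Arabidopsis thaliana accessions.
    Provides genotype and kinship containers, marker-based population
    structure (PCA, spatial autocorrelation by Moran's I, Ward
    clustering into genetic groups), linear mixed models for designed
    bioassays with genotypic predicted means and derived stress-response
    variables, marker-based narrow-sense heritability by REML,
    Bayesian kinship ("animal") mixed models fitted by Gibbs sampling
    with pMCMC inference for life-cycle, geographic-gradient and
    trade-off hypotheses, and a two-trait multi-trait mixed model
    (MTMM) genome-wide association scan with generalized least squares
    F tests and QTL window selection. A synthetic-data generator with
    isolation-by-distance genotype structure and known trait
    architecture supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    car,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
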