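Package: agenet
Title: Population Age Effects on the Genetic Structure of Patchy Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genetic analyses of habitat-age effects on
    microsatellite genetic structure in spatially isolated plant populations.
    Reads and quality-filters per-individual allele tables (tabular or GenePop),
    computes per-population diversity (rarefied allelic richness, observed and
    unbiased expected heterozygosity, inbreeding coefficient), three pairwise
    differentiation measures (standardized G''ST, shared-allele distance DPS,
    and conditional genetic distance through a pruned population graph),
    graph-topology metrics (normalized harmonic centrality, genetic-versus-
    geographic edge imbalance), Hanski incidence-function spatial connectivity,
    and a regression layer of random-intercept linear mixed models and
    maximum-likelihood population effects (MLPE) models with Box-Cox
    transformation, grouped standardization, all-subsets AICc selection and
    generalized variance-inflation checks. A forward-time Wright-Fisher
    simulator with stepwise microsatellite mutation, staggered population
    founding and distance-kernel migration generates synthetic landscapes for
    testing every stage without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
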