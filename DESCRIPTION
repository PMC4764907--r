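Package: salitype
Title: Diversity Stratification and Community Typing of Salivary
    Microbiome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for population-scale 16S
    rRNA gene salivary microbiome surveys. Provides rarefaction and
    alpha-diversity measures (observed OTUs, Shannon index, Faith's
    phylogenetic diversity), phylogenetic-diversity quintile
    stratification, prevalence-based identification of core and
    predominant-core OTUs, enterotype-style community typing of
    predominant-core relative-abundance profiles (square-root
    Jensen-Shannon distance, partitioning-around-medoids clustering,
    Calinski-Harabasz model selection, silhouette widths, PCA biplot
    coordinates), Pearson/FDR co-occurrence networks with cohabiting-group
    extraction, and a bivariate plus multivariate association layer
    (standardized multiple regression for diversity, modified Poisson
    prevalence-ratio regression for community type). A
    Dirichlet-multinomial simulator with planted community types, a
    core/rare prevalence hierarchy and covariate-linked diversity
    provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    cluster,
    optparse,
    picante,
    sandwich,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
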