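Package: msatclust
Title: Clustering Evaluation Machinery for Microsatellite Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate model-based inference of population structure from
    diploid multi-locus microsatellite genotypes. Provides GenePop and STRUCTURE-dialect
    input/output, a synthetic breed-genotype generator with Balding-Nichols drift,
    frequency-level admixture and inbreeding, exact Hardy-Weinberg tests (Guo-Thompson
    Markov chain and full enumeration), Weir-Cockerham F-statistics, genic
    differentiation tests, principal coordinates analysis, POWSIM-style power and
    type-I-error simulation, a Gibbs sampler for the basic admixture clustering model,
    Evanno delta-K diagnostics with a replicate-block convergence protocol,
    label-switching mode alignment, ghost-cluster detection, FLOCK-style iterative
    reallocation clustering with plateau stopping rules and hierarchical partitioning,
    and discriminant analysis of principal components with BIC-based cluster-number
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
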