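Package: mutorder
Title: Temporal Ordering of Somatic Mutations from Single-Cell Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the temporal order of somatic mutations from error-prone
    single-cell genotype matrices. A Kingman-coalescent Monte Carlo simulation
    supplies the prior over pairwise order relations (ancestral in either
    direction, or on distinct lineages), a false-discovery/allelic-dropout
    observation model supplies the likelihood, and Bayes theorem yields
    posterior probabilities for every site pair. The maximum-posterior
    mutation tree is extracted as the minimum-weight spanning arborescence of
    the directed order graph (Chu-Liu/Edmonds), the stem-time fraction to the
    most recent common ancestor is estimated by empirical Bayes, and tree
    stability is assessed by leave-one-out replication. Ships the 18-site by
    58-cell essential-thrombocythemia genotype table of Hou et al. (2012)
    <doi:10.1016/j.cell.2012.02.028> as a worked fixture, plus a forward
    simulator of the full generative model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
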