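Package: bondscope
Title: Topological Bond Descriptors and Machine Learning for Bond
    Dissociation Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes orientation-independent topological descriptors for
    covalent bonds (atom-type counts and atom-pair counts over distance
    spheres around a target bond, bond-breaking differences, and fragment
    descriptors) and uses them to train ultra-fast predictors of homolytic
    bond dissociation energies: random forests with out-of-bag validation
    and importance-based descriptor selection, and an ensemble of
    feed-forward neural networks with an associative memory correction.
    Includes bond-level dataset construction from BDE-annotated SDFiles,
    a per-bond-type fixed-value baseline, and a synthetic generator of
    valence-legal CHONS molecules with surrogate additive bond energies so
    the whole pipeline can be exercised without quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    nnet,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
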