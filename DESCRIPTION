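Package: gainLossML
Title: Maximum-Likelihood Models of Gene Gain, Loss and Duplication for
    Ancestral Gene-Content Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time Markov models of gene gain, loss and
    duplication on a rooted species tree, for inferring the probability
    that a gene was present in the last universal common ancestor (LUCA).
    Genes are encoded as phyletic vectors over the states absent (0),
    single copy (1) and multiple in-paralogs (m); binary models (B1, B2)
    and three-state models (M1, M2) are fitted per gene by maximum
    likelihood using Felsenstein's pruning algorithm, compared by AIC
    within a state-space family, and summarized as root-presence
    posteriors, loss-to-gain rate ratios and thresholded ancestral gene
    sets. A forward simulator generates count tables under the same
    Markov process for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'RateModel.R'
    'treeio.R'
    'PhyleticProfiles.R'
    'likelihood.R'
    'inference.R'
    'fitGeneContent.R'
    'simulate.R'
    'cli.R'
    'gainLossML-package.R'
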