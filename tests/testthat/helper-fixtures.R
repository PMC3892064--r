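# Shared fixtures: small trees and random model draws, all built in code.

# Five-leaf reference topology with all branch lengths 0.35: three
# cherries/internal nodes plus the root, eight edges in total.
fiveLeafTree <- function(t = 0.35) {
    parseNewick(sprintf(
        "(((A:%g,B:%g):%g,C:%g):%g,(D:%g,E:%g):%g);",
        t, t, t, t, t, t, t, t))
}

# Random rooted tree with uniform branch lengths in [tmin, tmax].
randomFixtureTree <- function(nLeaves, tmin = 0.01, tmax = 2) {
    tr <- ape::rtree(nLeaves, rooted = TRUE)
    tr$edge.length <- stats::runif(nrow(tr$edge), tmin, tmax)
    tr$tip.label <- paste0("sp", seq_len(nLeaves))
    tr
}

# Random rate draw for a model, rates uniform in [lo, hi].
randomRates <- function(model, lo = 0.05, hi = 5) {
    nm <- switch(model,
        B1 = "c", B2 = c("g", "l"),
        M1 = c("g1", "g2", "l1", "l2", "c"),
        M2 = c("g1", "g2", "l1", "l2", "c1", "c2"))
    RateModel(model, stats::setNames(stats::runif(length(nm), lo, hi),
                                     nm))
}

# Random phyletic state vector over the model's space, covering the
# tree's leaves.
randomVector <- function(tree, model) {
    space <- stateSpace(model)
    stats::setNames(sample(space, length(tree$tip.label),
                           replace = TRUE), tree$tip.label)
}

# Relative difference between two positive likelihood values.
relErr <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
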