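test_that("root priors take the documented defaults", {
    p3 <- makeRootPrior("three-state")
    expect_equal(priorProbs(p3),
                 c("0" = 0.5, "1" = 0.45, "m" = 0.05))
    p2 <- makeRootPrior("binary")
    expect_equal(priorProbs(p2), c("0" = 0.5, "1" = 0.5))
})

test_that("frequency weighting scales presence mass and renormalizes", {
    # a gene found in 87 of 103 genomes: weight 0.84 (two decimals)
    p <- makeRootPrior("three-state", nPresent = 87, nTotal = 103,
                       weighting = TRUE)
    w <- 87 / 103
    expect_equal(round(w, 2), 0.84)
    expected <- c(0.5, 0.45 * w, 0.05 * w) / (0.5 + 0.5 * w)
    expect_equal(unname(priorProbs(p)), expected, tolerance = 1e-12)
    # 9:1 internal presence ratio is preserved under mode "both"
    pr <- priorProbs(p)
    expect_equal(unname(pr["1"] / pr["m"]), 9, tolerance = 1e-12)

    # weight 1 leaves the prior unchanged
    p1 <- makeRootPrior("three-state", nPresent = 10, nTotal = 10,
                        weighting = TRUE)
    expect_equal(priorProbs(p1), priorProbs(makeRootPrior("three-state")))

    # mode "single" scales only state 1
    ps <- makeRootPrior("three-state", nPresent = 50, nTotal = 100,
                        weighting = TRUE, mode = "single")
    expected <- c(0.5, 0.45 * 0.5, 0.05) / (0.5 + 0.225 + 0.05)
    expect_equal(unname(priorProbs(ps)), expected, tolerance = 1e-12)

    expect_error(makeRootPrior("binary", nPresent = 11, nTotal = 10,
                               weighting = TRUE), "exceeds")
})

test_that("zero-rate chain: likelihood is the prior of the frozen state", {
    tr <- fiveLeafTree()
    m0 <- RateModel("M1", g1 = 0, g2 = 0, l1 = 0, l2 = 0, c = 0)
    allZero <- stats::setNames(rep("0", 5), tr$tip.label)
    res <- pruneLikelihood(tr, allZero, m0)
    expect_equal(exp(logLik(res)), 0.5, tolerance = 1e-12)
    post <- rootPosterior(res)
    expect_equal(unname(post$posterior), c(1, 0, 0))
    expect_equal(post$presenceProbability, 0)
    expect_identical(post$mapState, "0")
    # a non-constant vector is impossible when nothing can change
    mixed <- stats::setNames(c("0", "1", "0", "0", "0"), tr$tip.label)
    resMixed <- pruneLikelihood(tr, mixed, m0)
    expect_identical(logLik(resMixed), -Inf)
    expect_error(rootPosterior(resMixed), "impossible")
})

test_that("two-leaf binary case matches the hand-expanded sum", {
    t <- 0.6931
    tr <- parseNewick(sprintf("(L1:%g,L2:%g);", t, t))
    m <- RateModel("B2", g = 1, l = 1)
    v <- c(L1 = "1", L2 = "0")
    # enumeration over the two root states with the analytic two-state
    # probabilities: f = 0.5 (p01 p00 + p11 p10)
    e <- exp(-2 * t)
    pSame <- (1 + e) / 2; pDiff <- (1 - e) / 2
    fExpected <- 0.5 * (pDiff * pSame + pSame * pDiff)
    res <- pruneLikelihood(tr, v, m)
    expect_equal(exp(logLik(res)), fExpected, tolerance = 1e-12)
    oracle <- bruteForceLikelihood(tr, v, m)
    expect_equal(logLik(res), logLik(oracle), tolerance = 1e-12)
    # posterior recomputed from the oracle's root partials
    L0 <- oracle@rootPartials[1L, ]
    post <- rootPosterior(res)$posterior
    expect_equal(unname(post),
                 unname(0.5 * L0 / sum(0.5 * L0)), tolerance = 1e-12)
})

test_that("five-leaf three-state case agrees with full enumeration", {
    tr <- fiveLeafTree(0.35)
    m <- RateModel("M1", g1 = 1, g2 = 1, l1 = 1, l2 = 1, c = 1)
    v <- c(A = "0", B = "1", C = "1", D = "m", E = "1")
    res <- pruneLikelihood(tr, v, m)
    oracle <- bruteForceLikelihood(tr, v, m)
    expect_equal(exp(logLik(res)), exp(logLik(oracle)),
                 tolerance = 1e-12)
    expect_equal(rootPosterior(res)$posterior,
                 rootPosterior(oracle)$posterior, tolerance = 1e-12)
})

test_that("pruning equals enumeration across random instances", {
    set.seed(77)
    for (i in 1:50) {
        model <- sample(c("B1", "B2", "M1", "M2"), 1)
        rm <- randomRates(model)
        tr <- randomFixtureTree(sample(2:6, 1))
        v <- randomVector(tr, rm)
        f1 <- exp(logLik(pruneLikelihood(tr, v, rm)))
        f2 <- exp(logLik(bruteForceLikelihood(tr, v, rm)))
        expect_lt(relErr(f1, f2), 1e-9)
        expect_gt(f1, 0)
        expect_lte(f1, 1)
    }
})

test_that("enumeration refuses trees beyond the guard", {
    tr <- randomFixtureTree(12)  # 11 internal nodes when binary
    rm <- RateModel("B2", g = 1, l = 1)
    v <- randomVector(tr, rm)
    expect_error(bruteForceLikelihood(tr, v, rm), "internal nodes")
})

test_that("likelihood is invariant to child processing order", {
    tr <- fiveLeafTree(0.4)
    rot <- ape::rotate(tr, length(tr$tip.label) + 1L)  # swap root kids
    rm <- RateModel("M2", g1 = .4, g2 = 1.2, l1 = 2, l2 = .7, c1 = .2,
                    c2 = .9)
    v <- c(A = "1", B = "0", C = "m", D = "1", E = "0")
    expect_equal(logLik(pruneLikelihood(tr, v, rm)),
                 logLik(pruneLikelihood(rot, v, rm)),
                 tolerance = 1e-12)
})

test_that("scaled pruning stays exact on a 103-leaf star tree", {
    # on a star tree the likelihood factorizes, giving an independent
    # log-space formula to test the rescaling machinery against
    n <- 103
    tr <- ape::stree(n, "star")
    tr$edge.length <- rep(0.35, n)
    tr$tip.label <- paste0("sp", 1:n)
    rm <- RateModel("M2", g1 = .5, g2 = 1, l1 = 1.5, l2 = 2, c1 = .1,
                    c2 = .3)
    set.seed(9)
    v <- stats::setNames(sample(c("0", "1", "m"), n, replace = TRUE),
                         tr$tip.label)
    P <- transitionMatrix(rm, 0.35)
    pi <- priorProbs(makeRootPrior("three-state"))
    logTerms <- vapply(1:3, function(k)
        log(pi[k]) + sum(log(P[k, match(v, c("0", "1", "m"))])),
        numeric(1))
    mx <- max(logTerms)
    expected <- mx + log(sum(exp(logTerms - mx)))
    got <- logLik(pruneLikelihood(tr, v, rm))
    expect_equal(got, unname(expected), tolerance = 1e-9)
})

test_that("universal presence with weight 1 favors root presence", {
    tr <- fiveLeafTree(0.35)
    rm <- RateModel("M1", g1 = .5, g2 = .5, l1 = .5, l2 = .5, c = .1)
    v <- stats::setNames(rep("1", 5), tr$tip.label)
    prior <- makeRootPrior("three-state", nPresent = 5, nTotal = 5,
                           weighting = TRUE)
    post <- rootPosterior(pruneLikelihood(tr, v, rm, prior))
    expect_gt(post$presenceProbability, 0.5)
})

test_that("state-space mismatches are rejected", {
    tr <- fiveLeafTree()
    v3 <- c(A = "0", B = "1", C = "m", D = "1", E = "0")
    expect_error(pruneLikelihood(tr, v3, RateModel("B2", g = 1, l = 1)),
                 "state space")
    expect_error(
        pruneLikelihood(tr, binarizeStates(v3),
                        RateModel("B2", g = 1, l = 1),
                        prior = makeRootPrior("three-state")),
        "state space")
    expect_error(pruneLikelihood(tr, v3[-1L],
                                 RateModel("M1", g1 = 1, g2 = 1,
                                           l1 = 1, l2 = 1, c = 1)),
                 "missing")
})
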