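## Likelihood of a phyletic vector on the species tree.
##
## The model is generative: the root state y0 is drawn from the prior
## pi, and each child's state from the parent's row of P(t) for the
## connecting branch of length t. The likelihood of the observed leaf
## states X is f(X | theta) = sum_y0 pi(y0) L0(y0), where L0(y0) is the
## conditional likelihood of the leaves given root state y0, computed by
## Felsenstein's pruning algorithm. The root posterior is
## f(y0 = k | X, theta) = pi(k) L0(k) / f(X | theta).

#' Prior over the root (LUCA) state
#'
#' @slot probs Named probability vector over the states, in fixed state
#'   order ("0","1") or ("0","1","m").
#' @slot weighted Was frequency weighting applied?
#' @slot weight The occurrence frequency n_present / n_total used (1
#'   when unweighted).
#' @slot mode How the weight is shared among presence states:
#'   \code{"both"} or \code{"single"}.
#' @seealso [makeRootPrior()]
#' @export
setClass("RootPrior",
    representation(probs = "numeric", weighted = "logical",
                   weight = "numeric", mode = "character"))

setValidity("RootPrior", function(object) {
    p <- object@probs
    if (!length(p) %in% 2:3 || is.null(names(p)))
        return("probs must be a named vector over 2 or 3 states")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
        return("prior probabilities must be >= 0 and sum to 1")
    TRUE
})

setMethod("show", "RootPrior", function(object) {
    cat(sprintf("RootPrior (%s%s): %s\n",
        if (length(object@probs) == 2L) "binary" else "three-state",
        if (object@weighted)
            sprintf(", weighted w = %.4g, mode = %s", object@weight,
                    object@mode) else "",
        paste(sprintf("pi(%s) = %.4g", names(object@probs),
                      object@probs), collapse = ", ")))
})

#' @describeIn RootPrior-class the probability vector
#' @param object A \code{RootPrior}.
#' @export
setMethod("priorProbs", "RootPrior", function(object) object@probs)

#' @describeIn RootPrior-class state labels of the prior
#' @export
setMethod("stateSpace", "RootPrior", function(object)
    names(object@probs))

#' Build the root-state prior, optionally frequency-weighted
#'
#' The default three-state prior is pi(0) = 0.5, pi(1) = 0.45,
#' pi(m) = 0.05 — presence states in a 9:1 ratio of single copy to
#' in-paralogs, reflecting the expectation that LUCA had relatively few
#' duplicated genes. The binary default is a flat (0.5, 0.5). With
#' \code{weighting = TRUE} the presence mass is multiplied by the gene's
#' occurrence frequency w = nPresent / nTotal and the prior is
#' renormalized; this guards against implausible absence calls for genes
#' found in nearly all genomes. \code{mode = "both"} (default) scales
#' states 1 and m jointly, preserving their 9:1 internal ratio;
#' \code{mode = "single"} scales only state 1.
#'
#' @param stateSpace \code{"three-state"} or \code{"binary"}.
#' @param nPresent Number of genomes where the gene occurs (state != 0).
#' @param nTotal Total number of genomes.
#' @param weighting Apply frequency weighting?
#' @param mode \code{"both"} or \code{"single"} (three-state only).
#' @param base Optional override of the unweighted prior (named numeric
#'   over the state space).
#' @return A [RootPrior-class].
#' @examples
#' makeRootPrior("three-state")                      # (0.5, 0.45, 0.05)
#' makeRootPrior("three-state", 87, 103, weighting = TRUE)
#' @export
makeRootPrior <- function(stateSpace = c("three-state", "binary"),
                          nPresent = NULL, nTotal = NULL,
                          weighting = FALSE,
                          mode = c("both", "single"), base = NULL) {
    stateSpace <- match.arg(stateSpace)
    mode <- match.arg(mode)
    states <- if (stateSpace == "binary") c("0", "1") else c("0", "1", "m")
    if (is.null(base)) {
        base <- if (stateSpace == "binary")
            c("0" = 0.5, "1" = 0.5)
        else c("0" = 0.5, "1" = 0.45, "m" = 0.05)
    } else {
        if (!setequal(names(base), states))
            stop("base prior must be named over: ",
                 paste(states, collapse = ", "))
        base <- base[states] / sum(base)
    }
    w <- 1
    if (weighting) {
        if (is.null(nPresent) || is.null(nTotal))
            stop("weighting requires nPresent and nTotal")
        if (nTotal < 1L || nPresent < 0L)
            stop("need 0 <= nPresent <= nTotal, nTotal >= 1")
        if (nPresent > nTotal)
            stop("nPresent exceeds nTotal")
        w <- nPresent / nTotal
        p <- base
        if (stateSpace == "binary" || mode == "both") {
            p[setdiff(states, "0")] <- p[setdiff(states, "0")] * w
        } else {
            p["1"] <- p["1"] * w
        }
        base <- p / sum(p)
    }
    new("RootPrior", probs = base, weighted = weighting, weight = w,
        mode = mode)
}

#' Result of a likelihood evaluation at the root
#'
#' @slot logLik Log-likelihood log f(X | theta) (per gene).
#' @slot rootPartials Matrix (genes x states) of root conditional
#'   likelihoods L0(k), each gene's row scaled by exp(-logScale).
#' @slot logScale Per-gene log of the scaling factor accumulated during
#'   pruning (0 for the brute-force path).
#' @slot prior The [RootPrior-class] used.
#' @export
setClass("LikelihoodResult",
    representation(logLik = "numeric", rootPartials = "matrix",
                   logScale = "numeric", prior = "RootPrior"))

setMethod("show", "LikelihoodResult", function(object) {
    cat(sprintf("LikelihoodResult: %d gene(s), logLik %s\n",
                length(object@logLik),
                paste(signif(utils::head(object@logLik, 5L), 6),
                      collapse = ", ")))
})

#' @export
setMethod("logLik", "LikelihoodResult", function(object, ...)
    object@logLik)

## Map observed state labels to column indices of the state space.
.stateIndex <- function(states, space) {
    idx <- match(states, space)
    if (anyNA(idx))
        stop("observed state(s) not in model state space {",
             paste(space, collapse = ", "), "}: ",
             paste(unique(states[is.na(idx)]), collapse = ", "))
    idx
}

## Coerce a single named vector or a genes x leaves matrix of state
## labels into an integer index matrix with columns ordered as
## tree$tip.label.
.stateMatrix <- function(v, tree, space) {
    if (!is.matrix(v))
        v <- matrix(v, 1L, dimnames = list("gene", names(v)))
    if (is.null(colnames(v)))
        stop("phyletic states must be named by leaf name")
    missingLeaves <- setdiff(tree$tip.label, colnames(v))
    if (length(missingLeaves))
        stop("leaves missing from the phyletic vector: ",
             paste(missingLeaves, collapse = ", "))
    extra <- setdiff(colnames(v), tree$tip.label)
    if (length(extra))
        stop("phyletic vector names not found in the tree: ",
             paste(extra, collapse = ", "))
    v <- v[, tree$tip.label, drop = FALSE]
    idx <- matrix(.stateIndex(v, space), nrow(v),
                  dimnames = dimnames(v))
    idx
}

## Transition matrices for a set of branch lengths, computed from one
## spectral decomposition of Q: P(t) = V diag(e^{lambda t}) V^-1, so
## vec(P(t)) = A %*% e^{lambda t} with A[(i,j), s] = V[i,s] V^-1[s,j].
## One accuracy probe against the scaling-and-squaring exponential
## guards the decomposition; ill-conditioned cases fall back to
## per-length Matrix::expm. Returns matrices aligned with `lens`.
.transitionSet <- function(Q, lens) {
    k <- nrow(Q)
    uniq <- unique(lens)
    Ps <- NULL
    eg <- tryCatch(eigen(Q), error = function(e) NULL)
    if (!is.null(eg)) {
        Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
        if (!is.null(Vi)) {
            A <- matrix(0 + 0i, k * k, k)
            for (s in seq_len(k))
                A[, s] <- as.vector(outer(eg$vectors[, s], Vi[s, ]))
            E <- exp(outer(eg$values, uniq))
            cols <- Re(A %*% E)
            # probe the reconstruction against the reference exponential
            probe <- matrix(cols[, which.max(uniq)], k, k)
            ref <- .expmQ(Q, max(uniq))
            if (max(abs(probe - ref)) <= 1e-10) {
                Ps <- lapply(seq_along(uniq), function(u) {
                    P <- matrix(cols[, u], k, k)
                    P[P < 0] <- 0
                    P[P > 1] <- 1
                    P / rowSums(P)
                })
            }
        }
    }
    if (is.null(Ps))
        Ps <- lapply(uniq, function(t) .expmQ(Q, t))
    Ps[match(lens, uniq)]
}

.edgeTransitions <- function(model, tree) {
    Q <- rateMatrix(model)
    .transitionSet(unname(Q), tree$edge.length)
}

## Precomputed traversal plan: postorder edges with matching branch
## lengths, reused across many likelihood evaluations during fitting.
.treePlan <- function(tree) {
    tord <- ape::reorder.phylo(tree, "postorder")
    list(edge = tord$edge, lens = tord$edge.length,
         nTip = length(tree$tip.label),
         nNode = length(tree$tip.label) + tree$Nnode,
         root = .rootNode(tree))
}

## Core pruning recursion on a precomputed plan.
.pruneCore <- function(plan, stateIdx, Q, prior, space) {
    k <- length(space)
    nTip <- plan$nTip
    nG <- nrow(stateIdx)
    tPs <- lapply(.transitionSet(Q, plan$lens), t)
    partial <- vector("list", plan$nNode)
    for (tip in seq_len(nTip)) {
        M <- matrix(0, nG, k)
        M[cbind(seq_len(nG), stateIdx[, tip])] <- 1
        partial[[tip]] <- M
    }
    logScale <- numeric(nG)
    for (e in seq_len(nrow(plan$edge))) {
        par <- plan$edge[e, 1L]
        ch <- plan$edge[e, 2L]
        lik <- partial[[ch]] %*% tPs[[e]]
        partial[[par]] <- if (is.null(partial[[par]])) lik
                          else partial[[par]] * lik
        # rescale to dodge underflow on large trees
        mx <- partial[[par]][, 1L]
        for (j in seq_len(k)[-1L]) mx <- pmax(mx, partial[[par]][, j])
        mx[mx == 0] <- 1
        partial[[par]] <- partial[[par]] / mx
        logScale <- logScale + log(mx)
    }
    L0 <- partial[[plan$root]]
    dimnames(L0) <- list(rownames(stateIdx), space)
    f <- as.vector(L0 %*% priorProbs(prior))
    ll <- unname(log(f) + logScale)
    names(ll) <- rownames(stateIdx)
    list(logLik = ll, rootPartials = L0, logScale = logScale)
}

## Convenience wrapper building the plan on the fly.
.pruneEngine <- function(tree, stateIdx, model, prior) {
    .pruneCore(.treePlan(tree), stateIdx, unname(rateMatrix(model)),
               prior, stateSpace(model))
}

#' Likelihood of phyletic vectors by Felsenstein pruning
#'
#' Computes f(X | theta) for one gene (named state vector) or many genes
#' at once (genes x leaves state matrix) via per-node conditional
#' likelihoods, with per-node rescaling so that trees with a hundred or
#' more leaves do not underflow.
#'
#' @param tree The rooted species tree ([ape::phylo]).
#' @param v Named character vector of states, or a genes x leaves
#'   character matrix with leaf names as colnames. States must lie in
#'   the model's state space.
#' @param model A [RateModel-class]; binary models pair with binary
#'   vectors, three-state models with 0/1/m vectors.
#' @param prior A [RootPrior-class] over the same state space; defaults
#'   to the unweighted prior of the model's state space.
#' @return A [LikelihoodResult-class]; \code{logLik()} gives the per-gene
#'   log-likelihood.
#' @examples
#' tr <- parseNewick("((A:0.2,B:0.2):0.2,C:0.4);")
#' m <- RateModel("B2", g = 1, l = 3)
#' logLik(pruneLikelihood(tr, c(A = "1", B = "1", C = "0"), m))
#' @export
pruneLikelihood <- function(tree, v, model, prior = NULL) {
    stopifnot(is(model, "RateModel"))
    space <- stateSpace(model)
    if (is.null(prior))
        prior <- makeRootPrior(
            if (length(space) == 2L) "binary" else "three-state")
    if (!identical(stateSpace(prior), space))
        stop("prior state space does not match the model (",
             paste(space, collapse = "/"), ")")
    idx <- .stateMatrix(v, tree, space)
    res <- .pruneEngine(tree, idx, model, prior)
    ll <- if (is.matrix(v)) res$logLik else unname(res$logLik)
    new("LikelihoodResult", logLik = ll,
        rootPartials = res$rootPartials, logScale = res$logScale,
        prior = prior)
}

#' Likelihood by explicit enumeration of ancestral states
#'
#' Sums pi(y0) times the product of edge transition probabilities over
#' every assignment of states to the internal nodes — the expansion of
#' the likelihood before any dynamic-programming simplification. This is
#' the independent oracle for [pruneLikelihood()]; it refuses trees with
#' more than 8 internal nodes (the sum has k^n terms).
#'
#' @inheritParams pruneLikelihood
#' @return A [LikelihoodResult-class] (logScale all zero).
#' @export
bruteForceLikelihood <- function(tree, v, model, prior = NULL) {
    stopifnot(is(model, "RateModel"))
    space <- stateSpace(model)
    if (is.null(prior))
        prior <- makeRootPrior(
            if (length(space) == 2L) "binary" else "three-state")
    if (!identical(stateSpace(prior), space))
        stop("prior state space does not match the model")
    if (tree$Nnode > 8L)
        stop("enumeration refused: ", tree$Nnode,
             " internal nodes (limit 8); use pruneLikelihood()")
    idx <- .stateMatrix(v, tree, space)
    k <- length(space)
    nTip <- length(tree$tip.label)
    internal <- nTip + seq_len(tree$Nnode)
    root <- .rootNode(tree)
    Ps <- .edgeTransitions(model, tree)
    pi <- priorProbs(prior)
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
    colnames(grid) <- as.character(internal)
    nG <- nrow(idx)
    L0 <- matrix(0, nG, k, dimnames = list(rownames(idx), space))
    f <- numeric(nG)
    for (g in seq_len(nG)) {
        nodeState <- integer(nTip + tree$Nnode)
        nodeState[seq_len(nTip)] <- idx[g, ]
        for (a in seq_len(nrow(grid))) {
            nodeState[internal] <- grid[a, ]
            pr <- 1
            for (e in seq_len(nrow(tree$edge))) {
                pr <- pr * Ps[[e]][nodeState[tree$edge[e, 1L]],
                                   nodeState[tree$edge[e, 2L]]]
            }
            y0 <- nodeState[root]
            L0[g, y0] <- L0[g, y0] + pr
            f[g] <- f[g] + pi[y0] * pr
        }
    }
    ll <- unname(log(f))
    if (is.matrix(v)) names(ll) <- rownames(idx)
    new("LikelihoodResult", logLik = ll, rootPartials = L0,
        logScale = numeric(nG), prior = prior)
}

#' Posterior distribution of the root (LUCA) state
#'
#' Bayes' rule at the root: f(y0 = k | X, theta) =
#' pi(k) L0(k) / f(X | theta). The derived presence probability is
#' 1 - posterior("0"), and the maximum-a-posteriori state is the state
#' assigned to LUCA.
#'
#' @param object A [LikelihoodResult-class].
#' @param ... Unused.
#' @return For a single gene, a list with \code{posterior} (named
#'   vector), \code{presenceProbability} and \code{mapState}; for many
#'   genes, a list with the posterior matrix and per-gene vectors.
#' @export
setMethod("rootPosterior", "LikelihoodResult", function(object, ...) {
    pi <- priorProbs(object@prior)
    num <- sweep(object@rootPartials, 2L, pi, `*`)
    f <- rowSums(num)
    if (any(f <= 0))
        stop("data impossible under the model (likelihood 0); ",
             "no posterior is defined")
    post <- num / f
    presence <- 1 - post[, "0"]
    map <- colnames(post)[max.col(post, ties.method = "first")]
    if (nrow(post) == 1L) {
        list(posterior = post[1L, ], presenceProbability = presence[[1L]],
             mapState = map[[1L]])
    } else {
        list(posterior = post, presenceProbability = presence,
             mapState = stats::setNames(map, rownames(post)))
    }
})
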