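## Per-gene maximum-likelihood estimation, AIC model choice, and
## ancestral-set assembly.
##
## Optimization is on log-rates within [log(1e-6), log(100)] with
## multi-start L-BFGS-B: one central start (all rates 1), seeded
## jittered starts, and — for the larger model of a nested pair — a warm
## start at the smaller model's optimum, which guarantees
## l(M2) >= l(M1) and l(B2) >= l(B1) up to optimizer tolerance.

.RATE_LOWER <- 1e-6
.RATE_UPPER <- 100

#' Maximum-likelihood fit of a rate model to phyletic data
#'
#' @slot geneId Gene id(s) covered by the fit ("pooled" fits carry all).
#' @slot model The fitted [RateModel-class] at the optimum.
#' @slot logLik Maximized total log-likelihood l.
#' @slot aic -2 l + 2 p with p the free-parameter count of the model.
#' @slot posterior Root-state posterior under the fitted rates (matrix,
#'   genes x states).
#' @slot prior The [RootPrior-class] used.
#' @slot convergence List: optimizer status, number of restarts, which
#'   start won, whether any rate sits on a bound (a non-identifiability
#'   signal).
#' @export
setClass("GeneFit",
    representation(geneId = "character", model = "RateModel",
                   logLik = "numeric", aic = "numeric",
                   posterior = "matrix", prior = "RootPrior",
                   convergence = "list"))

setMethod("show", "GeneFit", function(object) {
    cat(sprintf("GeneFit [%s] %s: logLik = %.4f, AIC = %.4f\n",
                paste(utils::head(object@geneId, 3L), collapse = ","),
                modelId(object@model), object@logLik, object@aic))
    print(signif(rates(object@model), 4))
    if (isTRUE(object@convergence$boundHit))
        cat("  note: rate estimate on a bound (possible",
            "non-identifiability)\n")
})

#' @describeIn GeneFit-class maximized log-likelihood
#' @param object A \code{GeneFit}.
#' @export
setMethod("logLik", "GeneFit", function(object, ...) object@logLik)

#' @describeIn GeneFit-class the fitted model
#' @export
setMethod("modelId", "GeneFit", function(object) modelId(object@model))

#' @describeIn GeneFit-class fitted rate vector
#' @export
setMethod("rates", "GeneFit", function(object) rates(object@model))

#' @describeIn GeneFit-class Akaike information criterion of the fit,
#'   AIC = -2 l + 2 p (p = 1, 2, 5, 6 for B1, B2, M1, M2)
#' @param ... Unused.
#' @export
setMethod("aicScore", "GeneFit", function(object, ...) object@aic)

#' @describeIn GeneFit-class root-state posterior under the fitted rates
#' @export
setMethod("rootPosterior", "GeneFit", function(object, ...) {
    if (nrow(object@posterior) == 1L) object@posterior[1L, ]
    else object@posterior
})

#' @describeIn GeneFit-class probability that the gene was present at
#'   the root, 1 - posterior("0")
#' @export
setMethod("presenceProbability", "GeneFit", function(object) {
    p <- 1 - object@posterior[, "0"]
    if (length(p) == 1L) p[[1L]] else p
})

#' @describeIn GeneFit-class aggregate loss-to-gain rate ratio (see
#'   [summarizeGene()])
#' @export
setMethod("lossGainRatio", "GeneFit", function(object)
    .lossGain(object@model)$aggregate)

## loss/gain ratios of a RateModel; aggregate pools all loss-direction
## rates over all gain-direction rates.
.lossGain <- function(model) {
    r <- rates(model)
    switch(modelId(model),
        B1 = list(aggregate = 1, pairs = c(l_over_g = 1)),
        B2 = list(aggregate = unname(r["l"] / r["g"]),
                  pairs = c(l_over_g = unname(r["l"] / r["g"]))),
        M1 = {
            loss <- r["l1"] + r["l2"] + r["c"]
            gain <- r["g1"] + r["g2"] + r["c"]
            list(aggregate = unname(loss / gain),
                 pairs = c(l1_over_g1 = unname(r["l1"] / r["g1"]),
                           l2_over_g2 = unname(r["l2"] / r["g2"]),
                           c2_over_c1 = 1))
        },
        M2 = {
            loss <- r["l1"] + r["l2"] + r["c2"]
            gain <- r["g1"] + r["g2"] + r["c1"]
            list(aggregate = unname(loss / gain),
                 pairs = c(l1_over_g1 = unname(r["l1"] / r["g1"]),
                           l2_over_g2 = unname(r["l2"] / r["g2"]),
                           c2_over_c1 = unname(r["c2"] / r["c1"]))) })
}

## Q from a raw rate vector in canonical parameter order (no S4
## overhead; the optimizer calls this thousands of times).
.buildQraw <- function(modelName, r) {
    switch(modelName,
        B1 = matrix(c(-r[1L], r[1L], r[1L], -r[1L]), 2L, 2L,
                    byrow = TRUE),
        B2 = matrix(c(-r[1L], r[1L], r[2L], -r[2L]), 2L, 2L,
                    byrow = TRUE),
        M1 = matrix(c(-(r[1L] + r[5L]), r[1L], r[5L],
                      r[3L], -(r[3L] + r[2L]), r[2L],
                      r[5L], r[4L], -(r[4L] + r[5L])), 3L, 3L,
                    byrow = TRUE),
        M2 = matrix(c(-(r[1L] + r[5L]), r[1L], r[5L],
                      r[3L], -(r[3L] + r[2L]), r[2L],
                      r[6L], r[4L], -(r[4L] + r[6L])), 3L, 3L,
                    byrow = TRUE))
}

## Negative pooled log-likelihood as a function of log-rates.
.makeObjective <- function(tree, idx, modelName, prior) {
    plan <- .treePlan(tree)
    space <- if (modelName %in% c("B1", "B2")) c("0", "1")
             else c("0", "1", "m")
    function(logRates) {
        Q <- .buildQraw(modelName, exp(logRates))
        ll <- .pruneCore(plan, idx, Q, prior, space)$logLik
        v <- -sum(ll)
        if (!is.finite(v)) v <- 1e10
        v
    }
}

#' Fit a gain/loss model to one gene or a pooled set of genes
#'
#' Maximizes the (summed, if \code{v} is a matrix) log-likelihood over
#' the model's rates by multi-start bounded quasi-Newton optimization on
#' log-rates. Rates are constrained to [1e-6, 100] per unit branch
#' length; an estimate sitting on a bound is reported as a
#' non-identifiability warning in the convergence slot, not silently
#' clipped. Pooled fits (shared rates, summed log-likelihoods) are the
#' recommended route for parameter-recovery studies: a single phyletic
#' vector carries little information about 5-6 rates.
#'
#' @param tree Rooted species tree ([ape::phylo]).
#' @param v Named state vector (one gene) or genes x leaves state matrix
#'   (pooled fit over all rows).
#' @param model Model name: "B1", "B2", "M1" or "M2".
#' @param prior [RootPrior-class]; default unweighted prior of the
#'   model's state space.
#' @param restarts Total number of optimization starts (>= 1): one
#'   central start plus seeded jittered starts.
#' @param seed Integer seed controlling the jittered starts.
#' @param warmStart Optional named rate vector used as an extra start —
#'   pass the optimum of the nested smaller model to guarantee nested
#'   likelihood dominance.
#' @return A [GeneFit-class].
#' @export
fitModel <- function(tree, v, model = c("M2", "M1", "B2", "B1"),
                     prior = NULL, restarts = 5L, seed = 1L,
                     warmStart = NULL) {
    model <- match.arg(model)
    space <- if (model %in% c("B1", "B2")) c("0", "1") else
        c("0", "1", "m")
    if (is.null(prior))
        prior <- makeRootPrior(
            if (length(space) == 2L) "binary" else "three-state")
    if (!identical(stateSpace(prior), space))
        stop("prior state space does not match model ", model)
    idx <- .stateMatrix(v, tree, space)
    if (all(idx == 1L))
        stop("non-identifiable: the phyletic vector(s) are all-absent; ",
             "gain/loss rates cannot be estimated")
    parNames <- .MODEL_PARAMS[[model]]
    np <- length(parNames)
    negll <- .makeObjective(tree, idx, model, prior)
    lower <- rep(log(.RATE_LOWER), np)
    upper <- rep(log(.RATE_UPPER), np)
    starts <- list(rep(0, np))
    if (restarts > 1L) {
        set.seed(seed)
        for (i in seq_len(restarts - 1L))
            starts[[i + 1L]] <- stats::rnorm(np, 0, 1)
    }
    if (!is.null(warmStart)) {
        ws <- .expandWarmStart(warmStart, model)
        if (!is.null(ws))
            starts[[length(starts) + 1L]] <-
                pmin(pmax(log(ws), lower), upper)
    }
    best <- NULL
    status <- character(length(starts))
    for (s in seq_along(starts)) {
        opt <- tryCatch(
            stats::optim(starts[[s]], negll, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         # factr * eps ~ 1e-8: stop when the
                         # log-likelihood improves by less than that
                         control = list(maxit = 500L,
                                        factr = 4.5e7)),
            error = function(e) NULL)
        if (is.null(opt)) { status[s] <- "error"; next }
        status[s] <- if (opt$convergence == 0L) "converged" else
            paste0("code", opt$convergence)
        better <- is.null(best) || opt$value < best$value - 1e-10 ||
            (abs(opt$value - best$value) <= 1e-10 &&
             sum(opt$par^2) < sum(best$par^2))
        if (better) { best <- opt; best$start <- s }
    }
    if (is.null(best))
        stop("optimizer failed on all ", length(starts), " starts (",
             paste(unique(status), collapse = ", "), ")")
    r <- exp(best$par)
    names(r) <- parNames
    fitted <- new("RateModel", model = model, rates = r)
    res <- pruneLikelihood(tree, v, fitted, prior)
    post <- rootPosterior(res)
    postM <- if (is.matrix(post$posterior)) post$posterior else
        matrix(post$posterior, 1L,
               dimnames = list(rownames(idx)[1L], space))
    ll <- sum(logLik(res))
    boundHit <- any(best$par <= lower + 1e-6) ||
        any(best$par >= upper - 1e-6)
    new("GeneFit",
        geneId = rownames(idx),
        model = fitted,
        logLik = ll,
        aic = -2 * ll + 2 * np,
        posterior = postM,
        prior = prior,
        convergence = list(status = status, nStarts = length(starts),
                           winningStart = best$start,
                           optimStatus = status[best$start],
                           boundHit = boundHit))
}

## Map a smaller model's rates into a start for the larger model.
.expandWarmStart <- function(rates, model) {
    eps <- .RATE_LOWER
    nm <- names(rates)
    out <- switch(model,
        B2 = if (setequal(nm, "c"))
            c(g = unname(rates["c"]), l = unname(rates["c"]))
        else if (setequal(nm, c("g", "l"))) rates,
        M2 = if (setequal(nm, c("g1", "g2", "l1", "l2", "c")))
            c(rates[c("g1", "g2", "l1", "l2")],
              c1 = unname(rates["c"]), c2 = unname(rates["c"]))
        else if (setequal(nm, .MODEL_PARAMS$M2)) rates,
        M1 = if (setequal(nm, .MODEL_PARAMS$M1)) rates,
        B1 = if (setequal(nm, "c")) rates)
    if (is.null(out)) return(NULL)
    pmax(unlist(out)[.MODEL_PARAMS[[model]]], eps)
}

#' Fit both models of a state-space family with nesting warm starts
#'
#' Fits B1 then B2 (binary family) or M1 then M2 (three-state family),
#' warm-starting the larger model at the smaller model's optimum so the
#' nested likelihood ordering holds by construction.
#'
#' @inheritParams fitModel
#' @param family \code{"three-state"} (M1, M2) or \code{"binary"}
#'   (B1, B2).
#' @return Named list of [GeneFit-class], e.g. \code{list(M1 = , M2 = )}.
#' @export
fitModelFamily <- function(tree, v, family = c("three-state", "binary"),
                           prior = NULL, restarts = 5L, seed = 1L) {
    family <- match.arg(family)
    models <- if (family == "binary") c("B1", "B2") else c("M1", "M2")
    small <- fitModel(tree, v, models[1L], prior = prior,
                      restarts = restarts, seed = seed)
    large <- fitModel(tree, v, models[2L], prior = prior,
                      restarts = restarts, seed = seed + 1L,
                      warmStart = rates(small))
    stats::setNames(list(small, large), models)
}

#' AIC of a log-likelihood
#'
#' @param object Maximized log-likelihood (numeric), or a
#'   [GeneFit-class] via the method.
#' @param p Number of free parameters.
#' @param ... Unused.
#' @return -2 l + 2 p.
#' @examples
#' aicScore(-100, p = 5)  # 210
#' @export
setMethod("aicScore", "numeric", function(object, p, ...)
    -2 * object + 2 * p)

#' Choose the AIC-preferred model within one family
#'
#' Minimum AIC wins; an exact tie goes to the model with fewer
#' parameters. Fits from different state-space families (e.g. M1 vs B2)
#' are refused: AIC only compares models fitted to the same data
#' encoding.
#'
#' @param fits List of [GeneFit-class] for the same gene(s) and family.
#' @return The preferred [GeneFit-class].
#' @export
selectModel <- function(fits) {
    stopifnot(length(fits) >= 1L)
    fams <- vapply(fits, function(f)
        length(stateSpace(f@model)), integer(1L))
    if (length(unique(fams)) != 1L)
        stop("cannot compare models across state-space families by AIC ",
             "(different data encodings)")
    ids <- lapply(fits, slot, "geneId")
    if (!all(vapply(ids, identical, logical(1L), ids[[1L]])))
        stop("fits must cover the same gene(s)")
    aics <- vapply(fits, aicScore, numeric(1L))
    ps <- vapply(fits, function(f) nParams(f@model), integer(1L))
    best <- order(aics, ps)[1L]
    fits[[best]]
}

#' Summarize a fitted gene
#'
#' Presence probability 1 - posterior("0"), the maximum-a-posteriori
#' root state, and the loss-to-gain rate ratio. The aggregate ratio
#' pools all loss-direction rates over all gain-direction rates —
#' (l1 + l2 + c2) / (g1 + g2 + c1) for M2, with c1 = c2 = c for M1,
#' l / g for B2, and 1 for B1 by construction; the per-pair ratios
#' l1/g1, l2/g2, c2/c1 are reported alongside. A zero denominator yields
#' \code{Inf} with \code{ratioInfinite = TRUE}.
#'
#' @param fit A [GeneFit-class].
#' @return A list: \code{geneId}, \code{model}, \code{logLik},
#'   \code{aic}, \code{posterior}, \code{presenceProbability},
#'   \code{mapState}, \code{lossGainRatio}, \code{pairRatios},
#'   \code{ratioInfinite}, \code{boundHit}.
#' @export
summarizeGene <- function(fit) {
    stopifnot(is(fit, "GeneFit"))
    lg <- .lossGain(fit@model)
    post <- fit@posterior
    map <- colnames(post)[max.col(post, ties.method = "first")]
    list(geneId = fit@geneId,
         model = modelId(fit@model),
         logLik = fit@logLik,
         aic = fit@aic,
         posterior = if (nrow(post) == 1L) post[1L, ] else post,
         presenceProbability = presenceProbability(fit),
         mapState = if (length(map) == 1L) map[[1L]] else map,
         lossGainRatio = lg$aggregate,
         pairRatios = lg$pairs,
         ratioInfinite = !is.finite(lg$aggregate),
         boundHit = isTRUE(fit@convergence$boundHit))
}

#' Assemble the ancestral gene set at a probability threshold
#'
#' The set LUCA-MLx: genes whose root presence probability under their
#' preferred model is at least \code{x} (inclusive). Thresholds nest:
#' raising x can only shrink the set.
#'
#' @param presence Named numeric vector of per-gene presence
#'   probabilities (names = gene ids).
#' @param x Threshold in [0, 1].
#' @return List with \code{threshold}, \code{members} (gene ids) and
#'   \code{size}.
#' @examples
#' buildAncestralSet(c(g1 = .9, g2 = .65, g3 = .7), 0.7)  # g1, g3
#' @export
buildAncestralSet <- function(presence, x) {
    stopifnot(is.numeric(presence), length(x) == 1L, x >= 0, x <= 1)
    if (is.null(names(presence)))
        stop("presence probabilities must be named by gene id")
    # genes without a fit (NA) cannot be members at any threshold
    presence <- presence[!is.na(presence)]
    members <- names(presence)[presence >= x]
    list(threshold = x, members = members, size = length(members))
}

#' Ancestral-set size across a grid of thresholds
#'
#' Counts members of the ancestral set for each threshold (default the
#' grid 0.5, 0.55, ..., 1.0). The series is non-increasing in x.
#'
#' @inheritParams buildAncestralSet
#' @param thresholds Numeric vector of thresholds.
#' @return data.frame with columns \code{threshold}, \code{nGenes}.
#' @export
ancestralCountSeries <- function(presence,
                                 thresholds = seq(0.5, 1, by = 0.05)) {
    n <- vapply(thresholds, function(x)
        buildAncestralSet(presence, x)$size, integer(1L))
    data.frame(threshold = thresholds, nGenes = n)
}

#' Entrywise-median transition matrices over fitted genes
#'
#' For each model represented among the fits, evaluates P(t) at every
#' gene's fitted rates and takes the entrywise median — a population
#' summary of how gene states change along a typical branch. The rows
#' of a median matrix need not sum to 1. The natural choice of \code{t}
#' is the median branch length of the species tree (reported by
#' [validateTree()]).
#'
#' @param fits List of [GeneFit-class] objects (possibly several
#'   models).
#' @param t Branch length at which to evaluate, > 0.
#' @return Named list (by model id) of k x k median matrices.
#' @export
medianTransitionSummary <- function(fits, t) {
    stopifnot(is.numeric(t), length(t) == 1L)
    if (t <= 0)
        stop("branch length t must be > 0")
    byModel <- split(fits, vapply(fits, modelId, character(1L)))
    lapply(byModel, function(fl) {
        Ps <- lapply(fl, function(f) transitionMatrix(f@model, t))
        arr <- simplify2array(Ps)
        med <- apply(arr, c(1L, 2L), stats::median)
        dimnames(med) <- dimnames(Ps[[1L]])
        med
    })
}
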