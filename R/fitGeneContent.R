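## High-level per-gene analysis: encode, fit both models of each
## requested family per gene, pick by AIC, summarize.

#' Per-gene ancestral gene-content analysis
#'
#' For every gene in a [PhyleticProfiles-class] object, fits the
#' requested model families (three-state M1/M2 on the 0/1/m vector,
#' binary B1/B2 on the binarized vector), selects the AIC-preferred
#' model within each family, and tabulates root posteriors, presence
#' probabilities and loss-to-gain ratios. Priors may be frequency
#' weighted per gene by its occurrence across genomes.
#'
#' @param profiles A [PhyleticProfiles-class] with a species tree
#'   attached.
#' @param families Character subset of \code{c("three-state",
#'   "binary")}.
#' @param weighting Weight each gene's root prior by its occurrence
#'   frequency n_present / n_total?
#' @param weightingMode \code{"both"} (scale states 1 and m jointly,
#'   keeping their 9:1 ratio) or \code{"single"} (scale state 1 only).
#' @param restarts Optimization starts per model fit.
#' @param seed Base seed; each gene/model uses a deterministic offset.
#' @param verbose Print per-gene progress?
#' @return A list with \code{table} (one row per gene x family;
#'   columns: gene_id, family, model, per-model logLik and AIC, fitted
#'   rates, posteriors, presence probability, loss/gain ratio,
#'   convergence flags) and \code{fits} (nested list of all
#'   [GeneFit-class] objects, \code{fits[[gene]][[model]]}).
#' @export
fitGeneContent <- function(profiles,
                           families = c("three-state", "binary"),
                           weighting = FALSE,
                           weightingMode = c("both", "single"),
                           restarts = 5L, seed = 1L, verbose = FALSE) {
    stopifnot(is(profiles, "PhyleticProfiles"))
    weightingMode <- match.arg(weightingMode)
    families <- match.arg(families, several.ok = TRUE)
    tree <- speciesTree(profiles)
    if (is.null(tree))
        stop("profiles must carry a species tree")
    statesM <- phyleticStates(profiles)
    nTotal <- ncol(statesM)
    rows <- list()
    fits <- list()
    for (g in seq_len(nrow(statesM))) {
        gid <- rownames(statesM)[g]
        vec3 <- statesM[g, ]
        nPresent <- sum(vec3 != "0")
        fits[[gid]] <- list()
        for (fam in families) {
            spaceName <- if (fam == "binary") "binary" else "three-state"
            v <- if (fam == "binary") binarizeStates(vec3) else vec3
            prior <- makeRootPrior(spaceName, nPresent = nPresent,
                                   nTotal = nTotal,
                                   weighting = weighting,
                                   mode = weightingMode)
            famFits <- tryCatch(
                fitModelFamily(tree, v, fam, prior = prior,
                               restarts = restarts,
                               seed = seed + 97L * g),
                error = function(e) e)
            if (inherits(famFits, "error")) {
                if (verbose)
                    message(gid, " [", fam, "]: ",
                            conditionMessage(famFits))
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = gid, family = fam, model = NA_character_,
                    error = conditionMessage(famFits))
                next
            }
            fits[[gid]][names(famFits)] <- famFits
            preferred <- selectModel(famFits)
            sm <- summarizeGene(preferred)
            post <- sm$posterior
            row <- data.frame(
                gene_id = gid,
                family = fam,
                model = sm$model,
                logLik = sm$logLik,
                aic = sm$aic,
                presence_probability = sm$presenceProbability,
                map_state = sm$mapState,
                loss_gain_ratio = sm$lossGainRatio,
                bound_hit = sm$boundHit,
                error = NA_character_)
            for (k in names(post))
                row[[paste0("posterior_", k)]] <- post[[k]]
            for (f2 in names(famFits)) {
                row[[paste0("logLik_", f2)]] <- logLik(famFits[[f2]])
                row[[paste0("aic_", f2)]] <- aicScore(famFits[[f2]])
            }
            th <- rates(preferred)
            for (p in names(th)) row[[paste0("rate_", p)]] <- th[[p]]
            rows[[length(rows) + 1L]] <- row
            if (verbose)
                message(sprintf(
                    "%s [%s]: %s preferred, P(present at root) = %.3f",
                    gid, fam, sm$model, sm$presenceProbability))
        }
    }
    # rbind of ragged data.frames: unify columns first
    allCols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
        for (cc in setdiff(allCols, names(r))) r[[cc]] <- NA
        r[allCols]
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab, fits = fits)
}
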