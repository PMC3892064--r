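## Forward simulation of gene states down the species tree: the
## generative counterpart of the likelihood. Root state ~ prior; each
## child's state ~ the parent's row of P(branch length). Node states
## (not event times) are simulated, which is exactly the process the
## pruning likelihood integrates over.

#' Simulate phyletic vectors under a gain/loss model
#'
#' Draws, for each gene, a root state from the prior and then states
#' down the tree from the rows of the transition matrices. True root and
#' internal-node states are retained for recovery studies. Counts are
#' emitted with 2 as the canonical representative of state m.
#'
#' @param tree Rooted species tree ([ape::phylo]).
#' @param model Generating [RateModel-class].
#' @param prior [RootPrior-class] for the root state; defaults to the
#'   unweighted prior of the model's state space.
#' @param nGenes Number of genes to simulate (>= 0).
#' @param seed Integer seed; fixed seed implies identical output.
#' @param geneIds Optional gene ids (default \code{gene0001}, ...).
#' @return A list: \code{counts} (integer matrix genes x genomes,
#'   states 0/1/m as counts 0/1/2), \code{states} (character matrix of
#'   leaf states), \code{rootStates}, \code{nodeStates} (genes x
#'   internal nodes, including the root column \code{root}),
#'   \code{model}, \code{prior}, \code{seed}.
#' @examples
#' tr <- parseNewick("((A:0.3,B:0.3):0.2,C:0.5);")
#' sim <- simulateGenes(tr, RateModel("B2", g = 1, l = 3), nGenes = 5,
#'                      seed = 42)
#' sim$counts
#' @export
simulateGenes <- function(tree, model, prior = NULL, nGenes,
                          seed = 1L, geneIds = NULL) {
    stopifnot(is(model, "RateModel"), nGenes >= 0)
    validateTree(tree)
    space <- stateSpace(model)
    if (is.null(prior))
        prior <- makeRootPrior(
            if (length(space) == 2L) "binary" else "three-state")
    if (!identical(stateSpace(prior), space))
        stop("prior state space does not match the model")
    if (is.null(geneIds))
        geneIds <- sprintf("gene%04d", seq_len(nGenes))
    stopifnot(length(geneIds) == nGenes)
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    root <- .rootNode(tree)
    k <- length(space)
    seed <- as.integer(seed)
    set.seed(seed)
    internal <- setdiff(seq_len(nNode), seq_len(nTip))
    internalNames <- ifelse(internal == root, "root",
                            paste0("node", internal))
    stateAt <- matrix(0L, nGenes, nNode)
    if (nGenes > 0L) {
        Ps <- .edgeTransitions(model, tree)
        # reversed postorder: every parent is assigned before its children
        ord <- rev(ape::postorder(tree))
        stateAt[, root] <- sample.int(k, nGenes, replace = TRUE,
                                      prob = priorProbs(prior))
        for (e in ord) {
            par <- tree$edge[e, 1L]
            ch <- tree$edge[e, 2L]
            cum <- t(apply(Ps[[e]], 1L, cumsum))
            u <- stats::runif(nGenes)
            parState <- stateAt[, par]
            # invert the per-parent-state CDF
            chState <- integer(nGenes)
            for (s in seq_len(k)) {
                sel <- parState == s
                if (any(sel))
                    chState[sel] <- 1L +
                        rowSums(outer(u[sel], cum[s, -k], `>`))
            }
            stateAt[, ch] <- chState
        }
    }
    leafStates <- matrix(space[stateAt[, seq_len(nTip)]],
                         nrow = nGenes, ncol = nTip,
                         dimnames = list(geneIds, tree$tip.label))
    counts <- matrix(c("0" = 0L, "1" = 1L, "m" = 2L)[leafStates],
                     nrow = nGenes, ncol = nTip,
                     dimnames = dimnames(leafStates))
    storage.mode(counts) <- "integer"
    nodeStates <- matrix(space[stateAt[, internal]],
                         nrow = nGenes, ncol = length(internal),
                         dimnames = list(geneIds, internalNames))
    rootStates <- stats::setNames(space[stateAt[, root]], geneIds)
    list(counts = counts, states = leafStates,
         rootStates = rootStates, nodeStates = nodeStates,
         model = model, prior = prior, seed = seed)
}

#' Simulate a dataset and write it to disk
#'
#' Writes a count table readable by [readCountTable()], a truth table
#' (true root state per gene plus the generating rates), and the
#' configuration used, so a run can be reproduced exactly.
#'
#' @inheritParams simulateGenes
#' @param dir Output directory (created if needed).
#' @return Invisibly, the simulation list from [simulateGenes()] plus
#'   \code{paths}.
#' @export
simulateDataset <- function(tree, model, prior = NULL, nGenes,
                            seed = 1L, dir) {
    sim <- simulateGenes(tree, model, prior, nGenes, seed)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    countsPath <- file.path(dir, "counts.tsv")
    truthPath <- file.path(dir, "truth.tsv")
    configPath <- file.path(dir, "config.yaml")
    writeCountTable(sim$counts, countsPath)
    truth <- data.frame(gene_id = rownames(sim$counts),
                        root_state = unname(sim$rootStates))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(list(
        command = "simulate",
        model = modelId(sim$model),
        rates = as.list(rates(sim$model)),
        prior = as.list(priorProbs(sim$prior)),
        n_genes = nGenes,
        seed = seed,
        tree = ape::write.tree(tree)), configPath)
    sim$paths <- c(counts = countsPath, truth = truthPath,
                   config = configPath)
    invisible(sim)
}
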