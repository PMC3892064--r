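## Species-tree input and validation. Trees are ape "phylo" objects,
## interpreted as rooted: the root node is the inference target (LUCA).

#' Parse a Newick string into a rooted species tree
#'
#' Thin wrapper around [ape::read.tree()] that additionally enforces the
#' contract required downstream: a single rooted tree, unique leaf
#' names, and a finite nonnegative branch length on every non-root edge.
#' A branch length attached to the root itself, if present in the
#' string, is ignored (the root is the inference target, not a node
#' evolved into). Polytomies are accepted.
#'
#' @param text A single Newick statement terminated by ";".
#' @return An [ape::phylo] object.
#' @examples
#' parseNewick("((A:0.1,B:0.2):0.3,C:0.4);")
#' @export
parseNewick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    tree <- tryCatch(ape::read.tree(text = text),
        error = function(e) stop("Newick parse error: ",
                                 conditionMessage(e), call. = FALSE))
    if (is.null(tree))
        stop("Newick parse error: no tree could be read from the string")
    if (inherits(tree, "multiPhylo")) {
        if (length(tree) != 1L)
            stop("expected exactly one Newick tree, found ", length(tree))
        tree <- tree[[1L]]
    }
    if (is.null(tree$edge.length))
        stop("tree validation error: branch lengths are missing")
    if (anyNA(tree$edge.length))
        stop("tree validation error: a non-root edge lacks a branch length")
    tree$root.edge <- NULL
    validateTree(tree)
    tree
}

#' Read a rooted species tree from a Newick file
#'
#' @param file Path to a file holding one Newick tree.
#' @return An [ape::phylo] object, validated as by [parseNewick()].
#' @export
readSpeciesTree <- function(file) {
    if (!file.exists(file))
        stop("tree file not found: ", file)
    parseNewick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Validate a species tree and summarize it
#'
#' Checks the invariants the likelihood machinery relies on (single
#' root, unique leaf names, at least two leaves, finite nonnegative
#' branch lengths) and returns a small report. The median branch length
#' in the report is the branch length at which transition-probability
#' summaries are evaluated by default (see
#' [medianTransitionSummary()]). The tree is never modified.
#'
#' @param tree An [ape::phylo] object.
#' @return Invisibly for side-effect-free use: a list with
#'   \code{nLeaves}, \code{nInternal}, \code{maxDepth} (edges from root
#'   to deepest leaf), and \code{branchLengths} (min, median, mean, max).
#' @examples
#' validateTree(parseNewick("((A:0.1,B:0.2):0.3,C:0.4);"))
#' @export
validateTree <- function(tree) {
    if (!inherits(tree, "phylo"))
        stop("tree must be an ape 'phylo' object")
    nTip <- length(tree$tip.label)
    if (nTip < 2L)
        stop("tree validation error: at least 2 leaves required")
    if (anyDuplicated(tree$tip.label))
        stop("tree validation error: duplicate leaf names: ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    if (is.null(tree$edge.length) || anyNA(tree$edge.length))
        stop("tree validation error: every non-root edge needs a branch ",
             "length")
    if (any(!is.finite(tree$edge.length)))
        stop("tree validation error: branch lengths must be finite")
    if (any(tree$edge.length < 0))
        stop("tree validation error: negative branch length")
    # exactly one root: one node that never appears as a child
    nodes <- seq_len(nTip + tree$Nnode)
    children <- tree$edge[, 2L]
    rootCandidates <- setdiff(nodes, children)
    if (length(rootCandidates) != 1L)
        stop("tree validation error: tree must have exactly one root")
    if (anyDuplicated(children))
        stop("tree validation error: a node has more than one parent")
    depths <- ape::node.depth.edgelength(tree)
    bl <- tree$edge.length
    list(nLeaves = nTip,
         nInternal = tree$Nnode,
         maxDepth = max(depths[seq_len(nTip)]),
         branchLengths = c(min = min(bl), median = stats::median(bl),
                           mean = mean(bl), max = max(bl)))
}

## Root node index of a phylo tree (the node that is never a child).
.rootNode <- function(tree) {
    nTip <- length(tree$tip.label)
    setdiff(seq_len(nTip + tree$Nnode), tree$edge[, 2L])
}
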