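## Phyletic vectors: per-gene records of gene state across genomes.
## Counts (0, 1, 2, ...) are reduced to states 0 / 1 / m (absent, single
## copy, multiple in-paralogs); binary analyses collapse m into 1.

#' Phyletic profiles of genes across genomes
#'
#' S4 container pairing a genes x genomes copy-count matrix with the
#' rooted species tree over those genomes, plus optional domain labels
#' (e.g. Bacteria / Archaea) used by [filterSingleDomain()].
#'
#' @slot counts Integer matrix, rows = genes (unique rownames), columns
#'   = genomes (unique colnames), entries = nonnegative copy counts.
#' @slot tree An [ape::phylo] species tree whose leaf names equal the
#'   column names, or \code{NULL} before a tree is attached.
#' @slot domains Named character vector mapping genome to domain label,
#'   or empty when no labels are supplied.
#'
#' @seealso [PhyleticProfiles()], [phyleticStates()], [fitGeneContent()]
#' @export
setClass("PhyleticProfiles",
    representation(counts = "matrix", tree = "ANY", domains = "character"))

setValidity("PhyleticProfiles", function(object) {
    cnt <- object@counts
    if (!is.numeric(cnt))
        return("counts must be a numeric matrix")
    if (is.null(rownames(cnt)) || anyDuplicated(rownames(cnt)))
        return("counts must have unique gene ids as rownames")
    if (is.null(colnames(cnt)) || anyDuplicated(colnames(cnt)))
        return("counts must have unique genome ids as colnames")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
        return("counts must be finite nonnegative integers")
    if (!is.null(object@tree)) {
        if (!inherits(object@tree, "phylo"))
            return("tree must be an ape 'phylo' object or NULL")
        if (!setequal(object@tree$tip.label, colnames(cnt)))
            return("tree leaf names must equal count-table genome names")
    }
    if (length(object@domains)) {
        if (is.null(names(object@domains)))
            return("domains must be named by genome id")
        extra <- setdiff(colnames(cnt), names(object@domains))
        if (length(extra))
            return(paste("unlabeled genomes:", paste(extra, collapse = ", ")))
    }
    TRUE
})

#' Construct a PhyleticProfiles object
#'
#' @param counts Genes x genomes matrix of nonnegative integer copy
#'   counts with gene ids as rownames and genome ids as colnames.
#' @param tree Optional [ape::phylo] species tree; leaf names must match
#'   the matrix column names exactly (case-sensitive).
#' @param domains Optional named character vector (genome id -> domain).
#' @return A [PhyleticProfiles-class] object.
#' @examples
#' cnt <- matrix(c(0L, 1L, 2L, 1L, 0L, 3L), 2, 3, byrow = TRUE,
#'               dimnames = list(c("g1", "g2"), c("A", "B", "C")))
#' PhyleticProfiles(cnt, parseNewick("((A:1,B:1):1,C:2);"))
#' @export
PhyleticProfiles <- function(counts, tree = NULL, domains = character()) {
    storage.mode(counts) <- "integer"
    if (!is.null(tree) && !is.null(colnames(counts)) &&
        setequal(tree$tip.label, colnames(counts)))
        counts <- counts[, tree$tip.label, drop = FALSE]
    new("PhyleticProfiles", counts = counts, tree = tree,
        domains = as.character(domains) |>
            stats::setNames(names(domains)))
}

#' @describeIn PhyleticProfiles-class the copy-count matrix
#' @param object A \code{PhyleticProfiles}.
#' @export
setMethod("geneCounts", "PhyleticProfiles", function(object) object@counts)

#' @describeIn PhyleticProfiles-class the species tree (or NULL)
#' @export
setMethod("speciesTree", "PhyleticProfiles", function(object) object@tree)

#' @describeIn PhyleticProfiles-class the domain labels (possibly empty)
#' @export
setMethod("domainLabels", "PhyleticProfiles", function(object)
    object@domains)

#' @describeIn PhyleticProfiles-class derive the phyletic state matrix;
#'   \code{binary = TRUE} collapses state m into 1.
#' @param binary Collapse multi-copy state into presence?
#' @param ... Unused.
#' @export
setMethod("phyleticStates", "PhyleticProfiles",
    function(object, binary = FALSE, ...) {
        st <- encodeCounts(object@counts)
        if (binary) binarizeStates(st) else st
    })

setMethod("show", "PhyleticProfiles", function(object) {
    cat(sprintf("PhyleticProfiles: %d genes x %d genomes\n",
                nrow(object@counts), ncol(object@counts)))
    cat(if (is.null(object@tree)) "  no species tree attached\n" else
        sprintf("  species tree with %d leaves\n",
                length(object@tree$tip.label)))
    if (length(object@domains))
        cat("  domains:", paste(sprintf("%s (%d)",
            names(table(object@domains)), table(object@domains)),
            collapse = ", "), "\n")
})

#' @export
setMethod("dim", "PhyleticProfiles", function(x) dim(x@counts))

#' @export
setMethod("[", "PhyleticProfiles", function(x, i, j, ..., drop = FALSE) {
    cnt <- x@counts[i, , drop = FALSE]
    new("PhyleticProfiles", counts = cnt, tree = x@tree,
        domains = x@domains)
})

#' Read a gene copy-count table from TSV
#'
#' Expected layout: header row of genome ids, first column gene ids,
#' integer cells. Cell values must be whole nonnegative numbers; the
#' offending row and column are named otherwise.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix (genes x genomes).
#' @export
readCountTable <- function(path) {
    if (!file.exists(path))
        stop("count table not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count table needs a gene-id column plus >= 1 genome column")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene id in count table: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(mat)))
        stop("duplicate genome column in count table")
    num <- suppressWarnings(apply(mat, 2L, as.numeric))
    if (!is.matrix(num)) num <- matrix(num, nrow = nrow(mat))
    bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "non-integer or negative count at gene '%s', genome '%s': '%s'",
            genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
            mat[bad[1L, 1L], bad[1L, 2L]]))
    }
    storage.mode(num) <- "integer"
    dimnames(num) <- list(genes, colnames(mat))
    num
}

#' Write a gene copy-count table as TSV
#'
#' Inverse of [readCountTable()]: first column \code{gene_id}, one
#' column per genome.
#'
#' @param counts Integer matrix (genes x genomes) with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCountTable <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Encode copy counts as phyletic states
#'
#' Count 0 -> state "0" (absent), count 1 -> state "1" (single copy),
#' count >= 2 -> state "m" (multiple in-paralogs).
#'
#' @param counts Nonnegative integer vector or matrix of copy counts.
#' @return Character vector/matrix of the same shape over
#'   \{"0","1","m"\}.
#' @examples
#' encodeCounts(c(0, 1, 5, 2))  # "0" "1" "m" "m"
#' @export
encodeCounts <- function(counts) {
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("counts must be finite nonnegative integers")
    st <- ifelse(counts == 0, "0", ifelse(counts == 1, "1", "m"))
    if (is.matrix(counts)) {
        st <- matrix(st, nrow(counts), dimnames = dimnames(counts))
    } else names(st) <- names(counts)
    st
}

#' Collapse a three-state phyletic vector to binary
#'
#' States "0" stay 0; "1" and "m" both become "1" (presence).
#'
#' @param states Character vector/matrix over \{"0","1","m"\}.
#' @return Character vector/matrix over \{"0","1"\}.
#' @examples
#' binarizeStates(c("0", "1", "m", "m"))  # "0" "1" "1" "1"
#' @export
binarizeStates <- function(states) {
    if (!all(states %in% c("0", "1", "m")))
        stop("states must be in {0, 1, m}")
    out <- ifelse(states == "0", "0", "1")
    if (is.matrix(states)) {
        out <- matrix(out, nrow(states), dimnames = dimnames(states))
    } else names(out) <- names(states)
    out
}

#' Read genome-to-domain labels from TSV
#'
#' Two columns: genome id, domain label (e.g. Bacteria / Archaea).
#'
#' @param path Path to the TSV file (header optional but recommended:
#'   \code{species_id}, \code{domain}).
#' @return Named character vector (genome id -> domain).
#' @export
readDomainLabels <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("domain label table needs two columns: species_id, domain")
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Drop genes confined to a single domain
#'
#' Genes observed (count >= 1) in only one domain of life carry no
#' information about the root when the root splits the domains; they are
#' removed before fitting. Genes observed in every domain are retained;
#' genes present in every genome are additionally flagged universal
#' (they remain in the analysis — their high ancestral probability
#' should emerge from the likelihood, not from a rule). Genes observed
#' nowhere belong to no domain and are reported separately as
#' \code{unobserved} (they are degenerate for fitting).
#'
#' @param object A [PhyleticProfiles-class] (with \code{domains} set) or
#'   a counts matrix.
#' @param domains Named character vector genome -> domain; taken from
#'   \code{object} when omitted.
#' @return A list: \code{retained} (object of the input's class),
#'   \code{droppedByDomain} (named list of gene-id vectors, one entry
#'   per domain, e.g. Bacteria-only), \code{universal} (gene ids present
#'   in all genomes), \code{unobserved} (all-zero gene ids, dropped).
#' @export
filterSingleDomain <- function(object, domains = NULL) {
    counts <- if (is(object, "PhyleticProfiles")) geneCounts(object)
              else object
    if (is.null(domains) && is(object, "PhyleticProfiles"))
        domains <- domainLabels(object)
    if (is.null(domains) || !length(domains))
        stop("domain labels are required for filtering")
    missing <- setdiff(colnames(counts), names(domains))
    if (length(missing))
        stop("unlabeled genomes: ", paste(missing, collapse = ", "))
    dom <- domains[colnames(counts)]
    domSet <- sort(unique(dom))
    present <- counts >= 1L
    # genes x domains presence indicator
    byDom <- vapply(domSet, function(d)
        rowSums(present[, dom == d, drop = FALSE]) > 0L,
        logical(nrow(counts)))
    if (!is.matrix(byDom)) byDom <- matrix(byDom, nrow = nrow(counts))
    nDom <- rowSums(byDom)
    keep <- nDom == length(domSet)
    droppedByDomain <- lapply(seq_along(domSet), function(j)
        rownames(counts)[nDom >= 1L & !keep & byDom[, j] & nDom == 1L])
    names(droppedByDomain) <- paste0(domSet, "-only")
    # with >2 domains a gene can span some but not all; keep spec's rule
    partial <- rownames(counts)[nDom > 1L & !keep]
    if (length(partial))
        droppedByDomain$`multi-domain-incomplete` <- partial
    universal <- rownames(counts)[rowSums(present) == ncol(counts)]
    unobserved <- rownames(counts)[nDom == 0L]
    retained <-
        if (is(object, "PhyleticProfiles")) object[keep, ]
        else counts[keep, , drop = FALSE]
    list(retained = retained, droppedByDomain = droppedByDomain,
         universal = universal, unobserved = unobserved)
}

#' Zero out a clade after an inferred horizontal transfer
#'
#' When a gene is known to have been horizontally transferred into a
#' clade, the presences in that recipient clade say nothing about the
#' root; the corresponding phyletic-vector entries are reset to absence
#' and inference is redone on the edited vector.
#'
#' @param v Named phyletic state vector (names = leaf names) or a named
#'   count vector; entries in the recipient clade are set to "0" (or 0).
#' @param tree The species tree ([ape::phylo]).
#' @param recipient Either a single leaf name, or a character vector of
#'   leaf names whose most recent common ancestor defines the recipient
#'   clade, or an internal node number.
#' @return The edited vector, same type and names as \code{v}.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' hgtEditVector(c(A = "1", B = "1", C = "1", D = "m"), tr, c("C", "D"))
#' @export
hgtEditVector <- function(v, tree, recipient) {
    stopifnot(inherits(tree, "phylo"))
    leaves <- .recipientLeaves(tree, recipient)
    if (is.null(names(v)) || !all(leaves %in% names(v)))
        stop("v must be named by the tree's leaf names")
    v[leaves] <- if (is.numeric(v)) 0L else "0"
    v
}

## Resolve a recipient specification to the leaf names it covers.
.recipientLeaves <- function(tree, recipient) {
    nTip <- length(tree$tip.label)
    if (is.numeric(recipient)) {
        node <- as.integer(recipient)
        if (length(node) != 1L || node < 1L || node > nTip + tree$Nnode)
            stop("unknown node id: ", recipient)
    } else {
        bad <- setdiff(recipient, tree$tip.label)
        if (length(bad))
            stop("unknown leaf name(s): ", paste(bad, collapse = ", "))
        if (length(recipient) == 1L)
            return(recipient)
        node <- ape::getMRCA(tree, recipient)
    }
    if (node <= nTip)
        return(tree$tip.label[node])
    desc <- .cladeLeaves(tree, node)
    tree$tip.label[desc]
}

## Tip indices descending from an internal node (inclusive of tips).
.cladeLeaves <- function(tree, node) {
    nTip <- length(tree$tip.label)
    todo <- node
    tips <- integer()
    while (length(todo)) {
        cur <- todo[[1L]]; todo <- todo[-1L]
        kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
        tips <- c(tips, kids[kids <= nTip])
        todo <- c(todo, kids[kids > nTip])
    }
    sort(tips)
}
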