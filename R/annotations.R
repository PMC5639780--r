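#' Propagate annotations to all ancestors (true-path closure)
#'
#' Under the true path rule a gene annotated to a term is implicitly
#' annotated to every ancestor of that term. This closes a raw set of
#' gene-term pairs (or an incompletely propagated binary matrix) under
#' the ancestor relation. The operation is idempotent.
#'
#' Annotation terms are first remapped through the ontology's
#' alternate-id map; pairs whose term is neither a primary nor an
#' alternate id are skipped with a warning reporting the count.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param annotations either a data.frame with character columns
#'   \code{gene}, \code{term} (as from [readAnnotationPairs()]) or a
#'   binary gene x term matrix with dimnames.
#' @param genes optional character vector fixing the gene universe and
#'   row order of the result.
#' @return binary gene x term matrix over all non-virtual terms of the
#'   DAG (columns in \code{dagTerms()} order, virtual root excluded).
#' @export
propagateAnnotations <- function(dag, annotations, genes = NULL) {
    if (is.matrix(annotations)) {
        if (is.null(genes)) genes <- rownames(annotations)
        idx <- which(annotations == 1, arr.ind = TRUE)
        annotations <- data.frame(
            gene = rownames(annotations)[idx[, 1L]],
            term = colnames(annotations)[idx[, 2L]],
            stringsAsFactors = FALSE)
    }
    if (!is.data.frame(annotations) || !all(c("gene", "term") %in% names(annotations)))
        stop("annotations must be a gene/term data.frame or a binary matrix")

    term <- as.character(annotations$term)
    remap <- term %in% names(dag@altIdMap)
    term[remap] <- dag@altIdMap[term[remap]]
    known <- term %in% dag@terms
    if (any(!known))
        warning(sum(!known), " annotation pair(s) skipped: unknown term id(s) ",
                paste(utils::head(unique(term[!known]), 3L), collapse = ", "))
    gene <- as.character(annotations$gene)[known]
    term <- term[known]

    if (is.null(genes)) genes <- unique(as.character(annotations$gene))
    keepTerms <- setdiff(dag@terms, dag@virtualRoot)
    labels <- matrix(0L, length(genes), length(keepTerms),
                     dimnames = list(genes, keepTerms))
    if (length(gene) > 0L) {
        anc <- .ancestorSets(dag)
        closed <- lapply(split(term, gene), function(ts) {
            unique(c(ts, unlist(anc[ts], use.names = FALSE)))
        })
        for (g in names(closed)) {
            ts <- setdiff(closed[[g]], dag@virtualRoot)
            labels[g, ts] <- 1L
        }
    }
    labels
}

#' Prune rarely annotated terms and re-wire the DAG
#'
#' Removes every non-root term annotated to fewer than \code{minCount}
#' genes (counts taken from the true-path-closed annotation matrix).
#' Removed terms are contracted out of the graph: each removed term's
#' parents are connected to its children, so each surviving term's new
#' parents are its nearest surviving ancestors and reachability from the
#' root is preserved. With \code{minCount = 0} the operation is the
#' identity.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param annotations true-path-closed binary gene x term matrix.
#' @param minCount minimum number of annotated genes a term needs to
#'   survive.
#' @return list with elements \code{dag} (pruned [OntologyDAG-class])
#'   and \code{annotations} (matrix restricted to surviving terms).
#' @export
pruneTerms <- function(dag, annotations, minCount) {
    realTerms <- setdiff(dag@terms, dag@virtualRoot)
    if (!all(realTerms %in% colnames(annotations)))
        stop("annotations must cover every term of the DAG")
    counts <- colSums(annotations[, realTerms, drop = FALSE] == 1)
    keep <- realTerms[counts >= minCount | realTerms == dag@root]
    keep <- union(keep, dag@virtualRoot)
    drop <- setdiff(dag@terms, keep)

    parents <- dag@parents
    children <- dag@children
    for (v in drop) {  # contract v: connect its parents to its children
        ps <- setdiff(parents[[v]], drop[drop == v])
        cs <- children[[v]]
        for (p in ps) children[[p]] <- unique(c(setdiff(children[[p]], v), cs))
        for (cc in cs) parents[[cc]] <- unique(c(setdiff(parents[[cc]], v), ps))
        parents[[v]] <- character(0)
        children[[v]] <- character(0)
    }
    keepOrd <- dag@terms[dag@terms %in% keep]
    edges <- do.call(rbind, c(list(matrix(character(0), ncol = 2L)),
        lapply(keepOrd, function(p) {
            cs <- intersect(children[[p]], keepOrd)
            if (length(cs) == 0L) NULL else cbind(parent = p, child = cs)
        })))
    newDag <- OntologyDAG(edges, terms = keepOrd,
                          altIdMap = dag@altIdMap[dag@altIdMap %in% keepOrd])
    if (!setequal(dagTerms(newDag), keepOrd))
        stop("pruning disconnected surviving term(s) from the root")
    list(dag = newDag,
         annotations = annotations[, setdiff(keepOrd, dag@virtualRoot),
                                   drop = FALSE])
}
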