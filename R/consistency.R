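#' List true-path-rule violations in a score matrix
#'
#' A score matrix is consistent when, for every gene and every edge
#' (parent, child), the child's score does not exceed the parent's.
#' Violations are flagged when \code{child - parent > tol}; the small
#' tolerance absorbs sub-epsilon floating-point noise from averaging.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param scores numeric gene x term matrix; its columns must be a
#'   subset of the DAG's terms (the virtual root may be absent: its
#'   score is defined as 1 and can never be violated from above).
#' @param tol violation tolerance (default \code{1e-9}).
#' @return data.frame with columns \code{gene}, \code{parent},
#'   \code{child}, \code{parentScore}, \code{childScore}; zero rows iff
#'   the matrix is consistent.
#' @export
checkConsistency <- function(dag, scores, tol = 1e-9) {
    bad <- setdiff(colnames(scores), dag@terms)
    if (length(bad) > 0L)
        stop("score column(s) not in ontology: ", paste(bad, collapse = ", "))
    edges <- dag@edges
    present <- edges[, "parent"] %in% colnames(scores) &
               edges[, "child"] %in% colnames(scores)
    edges <- edges[present, , drop = FALSE]
    out <- vector("list", nrow(edges))
    for (k in seq_len(nrow(edges))) {
        p <- edges[k, "parent"]; ch <- edges[k, "child"]
        viol <- which(scores[, ch] - scores[, p] > tol)
        if (length(viol) > 0L)
            out[[k]] <- data.frame(
                gene = rownames(scores)[viol], parent = p, child = ch,
                parentScore = scores[viol, p], childScore = scores[viol, ch],
                stringsAsFactors = FALSE, row.names = NULL)
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (length(out) == 0L)
        return(data.frame(gene = character(0), parent = character(0),
                          child = character(0), parentScore = numeric(0),
                          childScore = numeric(0)))
    do.call(rbind, out)
}

#' @rdname checkConsistency
#' @return \code{isConsistent()}: a single logical.
#' @export
isConsistent <- function(dag, scores, tol = 1e-9) {
    nrow(checkConsistency(dag, scores, tol)) == 0L
}
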