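#' Select the best-predicted, most specific ontology terms
#'
#' Keeps the terms whose per-term AUROC strictly exceeds
#' \code{aurocMin}, optionally restricted to the leaves of the DAG (the
#' most specific terms). This is the first stage of the candidate-gene
#' nomination procedure.
#'
#' @param report an [EvaluationReport-class] (or its \code{perTerm}
#'   data.frame with columns \code{term} and \code{auroc}).
#' @param dag an [OntologyDAG-class] object.
#' @param aurocMin AUROC cut-off (strict).
#' @param leavesOnly keep only terms without children.
#' @return character vector of selected term ids.
#' @export
selectBestTerms <- function(report, dag, aurocMin = 0.95, leavesOnly = TRUE) {
    pt <- if (methods::is(report, "EvaluationReport")) report@perTerm else report
    keep <- !is.na(pt$auroc) & pt$auroc > aurocMin
    terms <- pt$term[keep]
    terms <- intersect(terms, dag@terms)
    if (leavesOnly) terms <- intersect(terms, dagLeaves(dag))
    terms
}

#' Nominate unannotated candidate genes for one term
#'
#' Implements the five-step nomination rule: (1) sort all genes by
#' descending score (ties broken lexicographically by gene id so the
#' top set is well defined); (2) take the top \code{topK} genes, the set
#' S; (3) let A be the annotated genes within S; (4) let \eqn{\bar s} be
#' the maximum score in A; (5) report the unannotated genes in S scoring
#' \eqn{\ge \bar s} — or all of S when A is empty. A candidate therefore
#' outscores (or ties) every annotated gene among the top ranks, i.e.
#' the predictor believes in it at least as strongly as in any known
#' annotation.
#'
#' @param scores named numeric vector: corrected scores of every gene
#'   for the term.
#' @param annotated character vector of genes annotated to the term.
#' @param topK size of the top set S (default 5).
#' @return data.frame of candidates, columns \code{gene}, \code{score},
#'   ordered by decreasing score; attributes \code{sbar}, \code{nS},
#'   \code{nA} carry the per-term metadata.
#' @export
selectCandidateGenes <- function(scores, annotated, topK = 5L) {
    if (is.null(names(scores))) stop("scores must be a named gene vector")
    if (length(scores) < topK) {
        warning("fewer genes (", length(scores), ") than topK (", topK,
                "); using all")
        topK <- length(scores)
    }
    ord <- order(-scores, names(scores))
    top <- names(scores)[ord][seq_len(topK)]
    inA <- top %in% annotated
    if (!any(inA)) {
        cand <- top
        sbar <- NA_real_
    } else {
        sbar <- max(scores[top[inA]])
        cand <- top[!inA & scores[top] >= sbar]
    }
    out <- data.frame(gene = cand, score = as.numeric(scores[cand]),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "sbar") <- sbar
    attr(out, "nS") <- topK
    attr(out, "nA") <- sum(inA)
    out
}

#' Candidate-gene report over a set of terms
#'
#' Runs [selectCandidateGenes()] for each term and stacks the results.
#'
#' @param scores corrected gene x term score matrix.
#' @param annotations binary gene x term annotation matrix.
#' @param terms term ids to scan (e.g. from [selectBestTerms()]).
#' @param topK size of each term's top set.
#' @return data.frame with columns \code{term}, \code{gene},
#'   \code{score}, \code{sbar}, \code{nA}.
#' @export
candidateReport <- function(scores, annotations, terms, topK = 5L) {
    rows <- lapply(terms, function(tm) {
        ann <- rownames(annotations)[annotations[, tm] == 1]
        cand <- selectCandidateGenes(scores[, tm], ann, topK = topK)
        if (nrow(cand) == 0L) return(NULL)
        data.frame(term = tm, cand,
                   sbar = attr(cand, "sbar"), nA = attr(cand, "nA"),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0L)
        return(data.frame(term = character(0), gene = character(0),
                          score = numeric(0), sbar = numeric(0),
                          nA = integer(0)))
    do.call(rbind, rows)
}
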