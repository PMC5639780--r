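#' Gene-centric hierarchical precision and recall at one threshold
#'
#' For each annotated gene, the prediction set at threshold \eqn{\tau}
#' is every term scoring \eqn{\ge \tau}. Per-gene precision is the
#' fraction of predicted terms that are truly annotated; per-gene recall
#' is the fraction of annotated terms that are predicted. Recall is
#' averaged over all \eqn{N} genes with at least one annotation;
#' precision is by default averaged only over genes with a nonempty
#' prediction set (the 0/0 genes can instead be counted as precision 0
#' with \code{emptyGenes = "zero"}). The root term is excluded
#' throughout.
#'
#' @param scores numeric gene x term matrix.
#' @param annotations binary gene x term matrix over the same genes and
#'   terms.
#' @param tau score threshold.
#' @param root optional root term id to exclude (with it, any virtual
#'   root column is dropped too).
#' @param emptyGenes how genes with no prediction above \eqn{\tau} enter
#'   the precision average.
#' @return named numeric vector \code{c(precision, recall)}.
#' @export
geneCentricPrRc <- function(scores, annotations, tau, root = NULL,
                            emptyGenes = c("exclude", "zero")) {
    emptyGenes <- match.arg(emptyGenes)
    x <- .alignEval(scores, annotations, root)
    res <- .prRcGrid(x$scores, x$labels, tau, emptyGenes)
    c(precision = res$pr, recall = res$rc)
}

## Shared gene/term alignment and root exclusion for the gene-centric
## metrics. Genes without annotations (after root removal) are dropped.
.alignEval <- function(scores, annotations, root) {
    terms <- intersect(colnames(scores), colnames(annotations))
    terms <- setdiff(terms, root)
    genes <- intersect(rownames(scores), rownames(annotations))
    if (length(terms) == 0L || length(genes) == 0L)
        stop("scores and annotations share no usable genes/terms")
    L <- annotations[genes, terms, drop = FALSE]
    keep <- rowSums(L == 1) > 0
    if (!any(keep)) stop("no annotated genes to evaluate")
    list(scores = scores[genes, terms, drop = FALSE][keep, , drop = FALSE],
         labels = L[keep, , drop = FALSE])
}

.prRcGrid <- function(S, L, tau, emptyGenes) {
    P <- S >= tau
    tp <- rowSums(P & L == 1)
    npred <- rowSums(P)
    ntrue <- rowSums(L == 1)
    rc <- mean(tp / ntrue)
    has <- npred > 0
    pr <- if (emptyGenes == "exclude") {
        if (any(has)) mean(tp[has] / npred[has]) else 0
    } else {
        mean(ifelse(has, tp / pmax(npred, 1), 0))
    }
    list(pr = pr, rc = rc)
}

#' Maximum hierarchical F-score over a threshold grid
#'
#' \eqn{F_{max} = \max_\tau 2 Pr(\tau) Rc(\tau) / (Pr(\tau)+Rc(\tau))},
#' the CAFA gene-centric measure. The threshold is selected a
#' posteriori, so the measure is an optimistic upper bound on the
#' operating F-score. \eqn{F(\tau)} is defined as 0 where
#' \eqn{Pr + Rc = 0}; \eqn{\tau^*} is the smallest grid value attaining
#' the maximum.
#'
#' @inheritParams geneCentricPrRc
#' @param tauGrid threshold grid within [0,1].
#' @return list with \code{fmax}, \code{tau} (\eqn{\tau^*}),
#'   \code{precision} and \code{recall} at \eqn{\tau^*}.
#' @export
computeFmax <- function(scores, annotations, tauGrid = seq(0, 1, by = 0.01),
                        root = NULL, emptyGenes = c("exclude", "zero")) {
    emptyGenes <- match.arg(emptyGenes)
    if (length(tauGrid) == 0L || any(tauGrid < 0 | tauGrid > 1))
        stop("tauGrid must be a nonempty subset of [0,1]")
    x <- .alignEval(scores, annotations, root)
    tauGrid <- sort(tauGrid)
    pr <- rc <- numeric(length(tauGrid))
    for (k in seq_along(tauGrid)) {
        res <- .prRcGrid(x$scores, x$labels, tauGrid[k], emptyGenes)
        pr[k] <- res$pr; rc[k] <- res$rc
    }
    f <- ifelse(pr + rc == 0, 0, 2 * pr * rc / (pr + rc))
    best <- which.max(f)  # first (= smallest tau) maximum
    list(fmax = f[best], tau = tauGrid[best],
         precision = pr[best], recall = rc[best])
}

#' Term-centric AUROC (Mann-Whitney) for one term
#'
#' Area under the ROC curve of the gene ranking for one term, computed
#' as the Mann-Whitney statistic from mean ranks so that tied scores
#' contribute 1/2. Constant scores therefore give exactly 0.5.
#'
#' @param scores numeric score vector over genes.
#' @param labels binary label vector of the same length.
#' @return AUROC in [0,1]; \code{NA} if only one class is present.
#' @export
termAUROC <- function(scores, labels) {
    pos <- labels == 1
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Term-centric area under the precision-recall step curve
#'
#' Genes are ranked by decreasing score; at each distinct score cut the
#' precision and recall of the positive class are computed, and the area
#' is accumulated as \eqn{\sum_k (Rc_k - Rc_{k-1}) Pr_k} (ties are
#' handled by cutting at distinct score values only).
#'
#' @inheritParams termAUROC
#' @return AUPRC in [0,1]; \code{NA} if only one class is present.
#' @export
termAUPRC <- function(scores, labels) {
    pos <- labels == 1
    n1 <- sum(pos)
    if (n1 == 0L || sum(!pos) == 0L) return(NA_real_)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- as.integer(pos[ord])
    keep <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each distinct score
    tp <- cumsum(y)[keep]
    np <- seq_along(s)[keep]
    prec <- tp / np
    rec <- tp / n1
    sum(diff(c(0, rec)) * prec)
}

#' Full gene-centric and term-centric evaluation
#'
#' Computes per-term AUROC and AUPRC over the gene ranking of each term
#' (terms with a single class are reported as \code{NA} with a warning
#' and excluded from the summary means), the gene-centric Fmax with its
#' threshold \eqn{\tau^*}, and per-gene precision/recall/F at
#' \eqn{\tau^*}. The root term (and any virtual root) is excluded from
#' the gene-centric metrics.
#'
#' @inheritParams computeFmax
#' @param dag optional [OntologyDAG-class]; supplies the root to exclude.
#' @return an [EvaluationReport-class] object.
#' @export
evaluateScores <- function(scores, annotations, dag = NULL,
                           tauGrid = seq(0, 1, by = 0.01), root = NULL,
                           emptyGenes = c("exclude", "zero")) {
    emptyGenes <- match.arg(emptyGenes)
    if (!is.null(dag)) root <- unique(c(root, dag@root, dag@virtualRoot))
    terms <- intersect(colnames(scores), colnames(annotations))
    genes <- intersect(rownames(scores), rownames(annotations))
    S <- scores[genes, terms, drop = FALSE]
    L <- annotations[genes, terms, drop = FALSE]

    auroc <- vapply(terms, function(j) termAUROC(S[, j], L[, j]), numeric(1))
    auprc <- vapply(terms, function(j) termAUPRC(S[, j], L[, j]), numeric(1))
    nSingle <- sum(is.na(auroc))
    if (nSingle > 0L)
        warning(nSingle, " single-class term(s) excluded from AUROC/AUPRC means")
    perTerm <- data.frame(term = terms, auroc = auroc, auprc = auprc,
                          row.names = NULL, stringsAsFactors = FALSE)

    fm <- computeFmax(scores, annotations, tauGrid = tauGrid, root = root,
                      emptyGenes = emptyGenes)
    x <- .alignEval(scores, annotations, root)
    P <- x$scores >= fm$tau
    tp <- rowSums(P & x$labels == 1)
    prG <- ifelse(rowSums(P) > 0, tp / pmax(rowSums(P), 1), NA_real_)
    rcG <- tp / rowSums(x$labels == 1)
    fG <- ifelse(!is.na(prG) & prG + rcG > 0, 2 * prG * rcG / (prG + rcG), 0)
    perGene <- data.frame(gene = rownames(x$scores), precision = prG,
                          recall = rcG, f = fG, row.names = NULL,
                          stringsAsFactors = FALSE)

    summary <- c(meanAUROC = mean(auroc, na.rm = TRUE),
                 meanAUPRC = mean(auprc, na.rm = TRUE),
                 fmax = fm$fmax, precision = fm$precision,
                 recall = fm$recall, tauStar = fm$tau)
    new("EvaluationReport", perTerm = perTerm, perGene = perGene,
        summary = summary)
}

#' @describeIn evaluateScores per-term AUROC/AUPRC table accessor
#' @param report an [EvaluationReport-class] object.
#' @export
perTerm <- function(report) report@perTerm

#' @describeIn evaluateScores per-gene metric table accessor
#' @export
perGene <- function(report) report@perGene

#' @describeIn evaluateScores summary metric vector accessor
#' @export
reportSummary <- function(report) report@summary

setMethod("show", "EvaluationReport", function(object) {
    s <- object@summary
    cat("EvaluationReport:", nrow(object@perTerm), "terms,",
        nrow(object@perGene), "genes\n")
    cat(sprintf("  mean AUROC %.4f | mean AUPRC %.4f\n",
                s["meanAUROC"], s["meanAUPRC"]))
    cat(sprintf("  Fmax %.4f at tau* = %.2f (Pr %.4f, Rc %.4f)\n",
                s["fmax"], s["tauStar"], s["precision"], s["recall"]))
    invisible(NULL)
})
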