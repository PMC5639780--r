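#' Maximum normalization of a score matrix
#'
#' Divides each term's column by its own maximum so that the column
#' maximum becomes exactly 1; within-column ordering is preserved.
#' All-zero columns are left untouched with a warning.
#'
#' @param scores numeric gene x term matrix with non-negative entries.
#' @return normalized matrix of the same shape.
#' @export
normalizeMax <- function(scores) {
    if (any(scores < 0)) stop("max normalization expects non-negative scores")
    mx <- apply(scores, 2L, max)
    zero <- mx == 0
    if (any(zero))
        warning(sum(zero), " all-zero column(s) left unnormalized")
    mx[zero] <- 1
    sweep(scores, 2L, mx, `/`)
}

#' Quantile normalization of a score matrix
#'
#' Maps every term column onto the common reference distribution (the
#' mean of the column-wise sorted values), making score magnitudes
#' comparable across terms; afterwards all columns share identical
#' sorted values. Ties within a column receive the mean of the reference
#' values they span. The computation is delegated to
#' \code{limma::normalizeQuantiles}.
#'
#' @param scores numeric gene x term matrix.
#' @param margin \code{"terms"} (default: columns are the distributions
#'   being equalized, i.e. scores are made comparable across terms) or
#'   \code{"genes"}.
#' @return normalized matrix of the same shape and dimnames.
#' @export
normalizeQuantile <- function(scores, margin = c("terms", "genes")) {
    margin <- match.arg(margin)
    m <- if (margin == "genes") t(scores) else scores
    if (ncol(m) < 2L) {
        warning("quantile normalization needs >= 2 columns; returning input")
        return(scores)
    }
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    if (margin == "genes") t(out) else out
}

#' Gene similarity network from binary feature annotations
#'
#' Edge weight between two genes is the Jaccard index of their feature
#' sets: the number of shared features over the number of features
#' carried by either gene (0 when both sets are empty). Two genes are
#' similar when they share most of their annotations.
#'
#' @param features binary gene x feature matrix with gene rownames.
#' @return symmetric gene x gene weight matrix in [0,1]; the diagonal is
#'   1 for every gene with at least one feature.
#' @export
jaccardNetwork <- function(features) {
    if (!all(features %in% c(0, 1)))
        stop("feature matrix must be binary (0/1)")
    m <- matrix(as.numeric(features), nrow(features),
                dimnames = dimnames(features))
    inter <- m %*% t(m)
    size <- rowSums(m)
    union <- outer(size, size, `+`) - inter
    w <- ifelse(union == 0, 0, inter / union)
    dimnames(w) <- list(rownames(features), rownames(features))
    w
}

#' Unweighted-average integration of gene networks
#'
#' Aligns all networks on the union of their gene sets (absent genes and
#' edges contribute weight 0), min-max normalizes each network's weights
#' into [0,1], and averages them edge-wise:
#' \eqn{\bar w_{ij} = \frac{1}{n}\sum_d w^d_{ij}}.
#'
#' @param networks list of symmetric weight matrices with gene dimnames.
#' @return symmetric gene x gene matrix over the union of genes.
#' @export
uaIntegrate <- function(networks) {
    if (length(networks) == 0L) stop("at least one network is required")
    genes <- sort(unique(unlist(lapply(networks, rownames))))
    acc <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
    for (w in networks) {
        full <- matrix(0, length(genes), length(genes),
                       dimnames = list(genes, genes))
        full[rownames(w), colnames(w)] <- .minMax(w)
        acc <- acc + full
    }
    acc / length(networks)
}

## Min-max map onto [0,1] over all entries; a constant positive matrix
## maps to all-1, a constant zero matrix stays zero.
.minMax <- function(w) {
    lo <- min(w); hi <- max(w)
    if (hi == lo) {
        if (hi == 0) return(w)
        w[] <- 1
        return(w)
    }
    (w - lo) / (hi - lo)
}

#' Kernel-smoothed neighborhood score for a term's positive genes
#'
#' A simple network-propagation flat scorer so the pipeline runs end to
#' end without an external learner: the adjacency matrix is
#' symmetrically degree-normalized, \eqn{S = D^{-1/2} W D^{-1/2}}
#' (isolated genes get self-degree 1), raised to the requested power,
#' and each gene is scored by its mean kernel affinity to the term's
#' positive genes; scores are then max-normalized. This is a generic
#' random-walk-kernel average, not a re-implementation of any specific
#' published ranking method.
#'
#' @param network symmetric gene x gene weight matrix.
#' @param positives character vector of positive (annotated) genes.
#' @param steps kernel power (1, 2 or 3 are typical).
#' @return named numeric score vector over all network genes, maximum 1.
#' @export
kernelAverageScore <- function(network, positives, steps = 1L) {
    if (length(positives) == 0L) stop("positive gene set must be nonempty")
    miss <- setdiff(positives, rownames(network))
    if (length(miss) > 0L)
        stop("positive gene(s) not in network: ", paste(miss, collapse = ", "))
    if (steps < 1L) stop("steps must be >= 1")
    d <- rowSums(network)
    d[d == 0] <- 1
    s <- network / sqrt(outer(d, d))
    k <- s
    for (i in seq_len(steps - 1L)) k <- k %*% s
    score <- rowMeans(k[, positives, drop = FALSE])
    mx <- max(score)
    if (mx > 0) score <- score / mx
    stats::setNames(as.numeric(score), rownames(network))
}
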