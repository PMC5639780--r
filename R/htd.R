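#' Hierarchical top-down (HTD-DAG) correction
#'
#' Corrects a flat gene x term score matrix so that it obeys the true
#' path rule. Terms are visited by increasing level (longest path from
#' the root) and each non-root score is capped by the minimum of its
#' parents' already-corrected scores:
#' \deqn{\bar y_i = \min(\hat y_i, \min_{j \in par(i)} \bar y_j)}
#' with \eqn{\bar y_{root} = \hat y_{root}}. Equivalently, the corrected
#' score of a term is the minimum flat score over the term and all its
#' ancestors. The output is always consistent, and the operation is
#' idempotent.
#'
#' Levels must come from the maximum-distance level function; with
#' shortest-path levels a parent can be processed after its child and
#' consistency is lost, so such level maps are rejected (every edge must
#' satisfy level(child) > level(parent)). \code{checkLevels = FALSE}
#' disables the guard, which is only useful to demonstrate the failure.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param scores numeric gene x term flat score matrix, entries in
#'   [0,1]; columns must be exactly the DAG's terms (the virtual root
#'   column may be omitted and is treated as constant 1).
#' @param levels named integer level map; computed with
#'   [computeLevels()] when \code{NULL}.
#' @param checkLevels validate the level map against every edge.
#' @return corrected score matrix with the same dimnames as
#'   \code{scores}.
#' @examples
#' dag <- OntologyDAG(rbind(c("r", "a"), c("a", "b")))
#' flat <- matrix(c(1, 0.3, 0.7), 1, dimnames = list("g1", c("r", "a", "b")))
#' htdCorrect(dag, flat)   # b capped at 0.3
#' @export
htdCorrect <- function(dag, scores, levels = NULL, checkLevels = TRUE) {
    scores <- .alignScores(dag, scores)
    if (is.null(levels)) levels <- computeLevels(dag)
    if (checkLevels) .assertMaxLevels(dag, levels)
    ord <- names(sort(levels[dag@terms]))
    work <- scores$m
    for (v in ord) {
        ps <- dag@parents[[v]]
        if (length(ps) == 0L) next
        pmin_ <- work[, ps[1L]]
        for (p in ps[-1L]) pmin_ <- pmin(pmin_, work[, p])
        work[, v] <- pmin(work[, v], pmin_)
    }
    .stripVirtual(dag, work, scores$hadVirtual)
}

## Shared input handling for the correction engines: verify the column
## set, check the [0,1] range, and add the virtual-root column (score 1).
.alignScores <- function(dag, scores) {
    if (is.null(colnames(scores)) || is.null(rownames(scores)))
        stop("score matrix must carry gene rownames and term colnames")
    expected <- setdiff(dag@terms, dag@virtualRoot)
    hadVirtual <- length(dag@virtualRoot) > 0L &&
        dag@virtualRoot %in% colnames(scores)
    want <- if (hadVirtual) dag@terms else expected
    if (!setequal(colnames(scores), want))
        stop("score matrix columns must match the ontology terms (",
             length(want), " expected, ", ncol(scores), " found)")
    if (any(scores < 0 | scores > 1))
        stop("flat scores must lie in [0,1]; rescale them first ",
             "(see normalizeMax)")
    m <- scores[, want[want %in% colnames(scores)], drop = FALSE]
    if (length(dag@virtualRoot) > 0L && !hadVirtual) {
        m <- cbind(m, matrix(1, nrow(m), 1L,
                             dimnames = list(rownames(m), dag@virtualRoot)))
    }
    list(m = m[, dag@terms, drop = FALSE], hadVirtual = hadVirtual)
}

.stripVirtual <- function(dag, m, hadVirtual) {
    if (length(dag@virtualRoot) > 0L && !hadVirtual)
        m <- m[, setdiff(colnames(m), dag@virtualRoot), drop = FALSE]
    m
}

.assertMaxLevels <- function(dag, levels) {
    if (!all(dag@terms %in% names(levels)))
        stop("level map must cover every term")
    e <- dag@edges
    if (nrow(e) > 0L && any(levels[e[, "parent"]] >= levels[e[, "child"]]))
        stop("level map is not a maximum-distance level function ",
             "(a parent's level >= its child's); recompute with ",
             "computeLevels(dag, distance = \"max\")")
    invisible(TRUE)
}
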