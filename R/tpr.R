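#' Build a TPR-DAG configuration
#'
#' @param variant one of \code{"TF"}, \code{"T"}, \code{"AT"},
#'   \code{"W"}, \code{"D"}; see [TPRConfig-class].
#' @param threshold constant threshold \eqn{\bar t} in (0,1), required
#'   for variants T and D (and for W with \code{childStrategy = "T"}).
#' @param weight parent weight \eqn{w} in [0,1], required for variant W.
#'   \code{weight = 1} makes TPR-W collapse exactly onto HTD-DAG.
#' @param childStrategy positive-children rule used by variant W.
#' @param atGrid thresholds searched by the adaptive (AT) strategy.
#' @param atMetric per-term metric maximized by AT (only "F").
#' @return a validated [TPRConfig-class] object.
#' @export
tprConfig <- function(variant = c("TF", "T", "AT", "W", "D"),
                      threshold = 0.5, weight = 0.5,
                      childStrategy = c("TF", "T", "AT"),
                      atGrid = seq(0.05, 0.95, by = 0.05),
                      atMetric = "F") {
    variant <- match.arg(variant)
    childStrategy <- match.arg(childStrategy)
    obj <- new("TPRConfig", variant = variant, threshold = threshold,
               weight = weight, childStrategy = childStrategy,
               atGrid = atGrid, atMetric = atMetric)
    methods::validObject(obj)
    obj
}

#' Select the "positive" children of a term for one gene
#'
#' Scalar form of the three positive-children rules, exposed mainly for
#' inspection and testing; [tprCorrect()] applies the same rules
#' vectorized over genes. All comparisons are strict: a child exactly at
#' its threshold is negative.
#'
#' \itemize{
#'   \item T: children with bottom-up score \eqn{> \bar t}.
#'   \item AT: children \eqn{j} with bottom-up score \eqn{> t_j^*}, the
#'     per-term threshold maximizing the training F-score
#'     (see [fitAdaptiveThresholds()]).
#'   \item TF: children whose bottom-up score exceeds the parent's own
#'     flat score — i.e. exactly the children able to raise it.
#' }
#'
#' @param childValues named numeric vector: bottom-up scores of the
#'   term's children for one gene.
#' @param parentFlat the parent term's flat score (used by TF).
#' @param strategy "T", "AT" or "TF".
#' @param threshold constant threshold (strategy T).
#' @param atThresholds named numeric vector of fitted per-term
#'   thresholds (strategy AT); must cover the children.
#' @return character vector of positive child ids.
#' @export
selectPositiveChildren <- function(childValues, parentFlat,
                                   strategy = c("TF", "T", "AT"),
                                   threshold = 0.5, atThresholds = NULL) {
    strategy <- match.arg(strategy)
    if (length(childValues) == 0L) return(character(0))
    pos <- switch(strategy,
        TF = childValues > parentFlat,
        T  = childValues > threshold,
        AT = {
            if (is.null(atThresholds))
                stop("adaptive-threshold strategy requires fitted thresholds ",
                     "(training annotations)")
            miss <- setdiff(names(childValues), names(atThresholds))
            if (length(miss) > 0L)
                stop("no fitted threshold for term(s): ",
                     paste(miss, collapse = ", "))
            childValues > atThresholds[names(childValues)]
        })
    names(childValues)[pos]
}

#' Bottom-up score update for one term of one gene
#'
#' The consensus between a term's flat score and its positive children.
#' Base variants average them,
#' \eqn{(\hat y_i + \sum_{j} \bar y_j) / (1 + |\phi_i|)}; the weighted
#' variant uses \eqn{w \hat y_i + (1-w)/|\phi_i| \sum_j \bar y_j}, and
#' returns \eqn{\hat y_i} unchanged when the positive set is empty
#' (where the weighted formula is undefined). Inputs in [0,1] always
#' yield a result in [0,1].
#'
#' @param flatScore the term's flat score \eqn{\hat y_i}.
#' @param positiveValues numeric vector of the positive children's
#'   bottom-up scores.
#' @param weight \code{NULL} for the plain average, or \eqn{w \in [0,1]}
#'   for the weighted update.
#' @return the updated score, a single numeric.
#' @examples
#' tprNodeUpdate(0.2, 0.8)                 # (0.2 + 0.8) / 2 = 0.5
#' tprNodeUpdate(0.9, c(0.1, 0.3), weight = 0)  # children-only vote: 0.2
#' @export
tprNodeUpdate <- function(flatScore, positiveValues = numeric(0), weight = NULL) {
    if (is.null(weight))
        return((flatScore + sum(positiveValues)) / (1 + length(positiveValues)))
    if (length(positiveValues) == 0L) return(flatScore)
    weight * flatScore + (1 - weight) * mean(positiveValues)
}

#' Fit per-term adaptive thresholds on training data
#'
#' For each term, scans a grid of thresholds and keeps the one
#' maximizing the F-score of the binary rule \code{score > t} against
#' the training labels (smallest grid value on ties). Thresholds are
#' fitted on flat training scores, since they must exist before the
#' bottom-up pass runs.
#'
#' @param scores numeric gene x term training score matrix.
#' @param annotations binary gene x term training label matrix covering
#'   the same genes.
#' @param grid candidate thresholds.
#' @return named numeric vector: term -> fitted threshold. Terms with no
#'   positive training gene keep the largest grid value (no child score
#'   can then be called positive on training evidence alone).
#' @export
fitAdaptiveThresholds <- function(scores, annotations,
                                  grid = seq(0.05, 0.95, by = 0.05)) {
    if (length(grid) == 0L) stop("threshold grid must be nonempty")
    common <- intersect(rownames(scores), rownames(annotations))
    if (length(common) == 0L)
        stop("no genes shared between scores and training annotations")
    sc <- scores[common, , drop = FALSE]
    grid <- sort(grid)
    out <- stats::setNames(rep.int(max(grid), ncol(sc)), colnames(sc))
    for (j in colnames(sc)) {
        y <- if (j %in% colnames(annotations)) annotations[common, j] else
            rep.int(0L, length(common))
        npos <- sum(y == 1)
        if (npos == 0L) next
        best <- -Inf; bestT <- max(grid)
        for (t in grid) {
            pred <- sc[, j] > t
            tp <- sum(pred & y == 1)
            f <- if (tp == 0L) 0 else {
                pr <- tp / sum(pred); rc <- tp / npos
                2 * pr * rc / (pr + rc)
            }
            if (f > best + 1e-12) { best <- f; bestT <- t }
        }
        out[j] <- bestT
    }
    out
}

#' True-path-rule (TPR-DAG) hierarchical correction
#'
#' Two strictly separated passes over the DAG. The bottom-up pass visits
#' terms from the deepest level up to the root, replacing each term's
#' score by the consensus of its flat score and its positive children
#' (or positive descendants, variant D) under the configured rule — this
#' propagates evidence from specific terms towards general ones but does
#' not by itself enforce consistency. The top-down pass then applies the
#' HTD-DAG correction to the intermediate scores, which guarantees the
#' true path rule. With variant W and \code{weight = 1} the bottom-up
#' pass is the identity and the result equals [htdCorrect()] exactly.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param scores numeric gene x term flat score matrix in [0,1].
#' @param config a [TPRConfig-class] from [tprConfig()].
#' @param annotations training annotation matrix, required when the
#'   adaptive-threshold strategy is used.
#' @param trainScores training flat scores used to fit adaptive
#'   thresholds; defaults to \code{scores} (in a hold-out setting pass
#'   the training split here together with its annotations).
#' @param levels optional precomputed maximum-distance level map.
#' @return corrected score matrix, consistent by construction.
#' @export
tprCorrect <- function(dag, scores, config = tprConfig("TF"),
                       annotations = NULL, trainScores = NULL,
                       levels = NULL) {
    methods::validObject(config)
    aligned <- .alignScores(dag, scores)
    flat <- aligned$m
    if (is.null(levels)) levels <- computeLevels(dag)
    .assertMaxLevels(dag, levels)

    strategy <- if (config@variant == "W") config@childStrategy
                else if (config@variant == "D") "T"
                else config@variant
    atThr <- NULL
    if (strategy == "AT" && config@variant != "D") {
        if (is.null(annotations))
            stop("adaptive-threshold strategy requires training annotations")
        atThr <- fitAdaptiveThresholds(
            if (is.null(trainScores)) .stripVirtual(dag, flat, aligned$hadVirtual)
            else trainScores,
            annotations, config@atGrid)
        if (length(dag@virtualRoot) > 0L && !(dag@virtualRoot %in% names(atThr)))
            atThr[dag@virtualRoot] <- max(config@atGrid)
    }
    descSets <- if (config@variant == "D") .descendantSets(dag) else NULL

    work <- flat
    ord <- names(sort(levels[dag@terms], decreasing = TRUE))
    for (v in ord) {
        if (length(dag@virtualRoot) > 0L && v == dag@virtualRoot)
            next  # the virtual root is a formal device: its score stays 1
        members <- if (config@variant == "D") descSets[[v]] else dag@children[[v]]
        if (length(members) == 0L) next   # leaves keep their flat score
        W <- work[, members, drop = FALSE]
        pos <- switch(strategy,
            TF = W > flat[, v],
            T  = W > config@threshold,
            AT = sweep(W, 2L, atThr[members], `>`))
        s <- rowSums(W * pos)
        k <- rowSums(pos)
        if (config@variant == "W") {
            w <- config@weight
            upd <- flat[, v]
            has <- k > 0
            upd[has] <- w * flat[has, v] + (1 - w) * s[has] / k[has]
            work[, v] <- upd
        } else {
            work[, v] <- (flat[, v] + s) / (1 + k)
        }
    }
    corrected <- htdCorrect(dag, work, levels = levels)
    .stripVirtual(dag, corrected, aligned$hadVirtual)
}

#' Select the TPR-W parent weight by internal cross-validation
#'
#' Splits the training genes into folds; for each candidate weight,
#' corrects each fold's flat scores with TPR-W (fitting any adaptive
#' thresholds on the remaining folds) and records the fold's Fmax
#' against the training annotations. Returns the weight with the best
#' mean Fmax (the smallest such weight on ties). Fold assignment is
#' drawn from R's RNG, so results are reproducible under
#' \code{set.seed()}.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param scores training flat score matrix.
#' @param annotations training annotation matrix (true-path closed).
#' @param weightGrid candidate weights in [0,1].
#' @param nFolds number of internal folds (>= 2).
#' @param childStrategy,threshold,atGrid passed to [tprConfig()].
#' @param tauGrid threshold grid for the internal Fmax evaluation.
#' @return the selected weight, with the per-weight mean CV Fmax curve
#'   attached as attribute \code{"cvFmax"}.
#' @export
tuneWeight <- function(dag, scores, annotations, weightGrid,
                       nFolds = 5, childStrategy = "TF", threshold = 0.5,
                       atGrid = seq(0.05, 0.95, by = 0.05),
                       tauGrid = seq(0, 1, by = 0.01)) {
    if (length(weightGrid) == 0L) stop("weight grid must be nonempty")
    genes <- rownames(scores)
    if (length(genes) < nFolds)
        stop("fewer genes (", length(genes), ") than folds (", nFolds, ")")
    fold <- sample(rep_len(seq_len(nFolds), length(genes)))
    root <- dag@root
    cv <- vapply(weightGrid, function(w) {
        cfg <- tprConfig("W", weight = w, childStrategy = childStrategy,
                         threshold = threshold, atGrid = atGrid)
        mean(vapply(seq_len(nFolds), function(f) {
            test <- genes[fold == f]; train <- genes[fold != f]
            corr <- tprCorrect(dag, scores[test, , drop = FALSE], cfg,
                               annotations = annotations[train, , drop = FALSE],
                               trainScores = scores[train, , drop = FALSE])
            computeFmax(corr, annotations[test, , drop = FALSE],
                        tauGrid = tauGrid, root = root)$fmax
        }, numeric(1)))
    }, numeric(1))
    best <- weightGrid[which.max(cv)]
    attr(best, "cvFmax") <- stats::setNames(cv, weightGrid)
    best
}
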