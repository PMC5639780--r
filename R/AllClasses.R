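#' OntologyDAG: a rooted directed acyclic graph of ontology terms
#'
#' Represents an ontology hierarchy as a DAG \eqn{G = <V, E>} with
#' parent-to-child edges, a single root, and a map from alternate
#' (superseded) term identifiers to primary identifiers. Multi-root edge
#' sets are supported by silently inserting a virtual root connected to
#' every source root; the virtual root is stripped from user-facing
#' outputs and its flat score is defined as 1.
#'
#' @slot terms character vector of term identifiers (topologically unordered).
#' @slot edges two-column character matrix, columns \code{parent}, \code{child}.
#' @slot root identifier of the (possibly virtual) root term.
#' @slot altIdMap named character vector: names are alternate ids, values
#'   are primary term ids.
#' @slot parents named list: for each term, the character vector of its parents.
#' @slot children named list: for each term, the character vector of its children.
#' @slot virtualRoot character; the id of the inserted virtual root, or
#'   \code{character(0)} when the input already had a single root.
#'
#' @seealso [OntologyDAG()] for construction, [parseOBO()], [computeLevels()]
#' @export
setClass("OntologyDAG",
    slots = c(
        terms       = "character",
        edges       = "matrix",
        root        = "character",
        altIdMap    = "character",
        parents     = "list",
        children    = "list",
        virtualRoot = "character"
    )
)

setValidity("OntologyDAG", function(object) {
    msg <- character(0)
    if (length(object@root) != 1L)
        msg <- c(msg, "exactly one root is required")
    if (nrow(object@edges) > 0L && ncol(object@edges) != 2L)
        msg <- c(msg, "edges must have two columns (parent, child)")
    edgeTerms <- unique(as.vector(object@edges))
    if (!all(edgeTerms %in% object@terms))
        msg <- c(msg, "edge endpoints must be members of terms")
    if (object@root %in% object@edges[, 2L])
        msg <- c(msg, "root must have no incoming edge")
    g <- .dagIgraph(object)
    if (!igraph::is_dag(g)) {
        cyc <- .findCycle(object@children)
        msg <- c(msg, paste0("graph contains a directed cycle: ",
                             paste(cyc, collapse = " -> ")))
    } else {
        reach <- igraph::subcomponent(g, object@root, mode = "out")$name
        miss <- setdiff(object@terms, reach)
        if (length(miss) > 0L)
            msg <- c(msg, paste0(length(miss),
                " term(s) unreachable from root (e.g. ", miss[1L], ")"))
    }
    if (length(object@altIdMap) > 0L && !all(object@altIdMap %in% object@terms))
        msg <- c(msg, "altIdMap values must be members of terms")
    if (length(msg) > 0L) msg else TRUE
})

#' TPRConfig: configuration for the TPR-DAG bottom-up pass
#'
#' Bundles the variant of the true-path-rule ensemble and its tuning
#' parameters. Variants: \code{"T"} (constant threshold), \code{"AT"}
#' (per-term adaptive thresholds fitted on training data), \code{"TF"}
#' (threshold free: a child is positive when its bottom-up score exceeds
#' the parent's flat score), \code{"W"} (weighted average between the
#' parent's flat score and the positive-children mean), and \code{"D"}
#' (positive descendants instead of positive children).
#'
#' @slot variant one of "T", "AT", "TF", "W", "D".
#' @slot threshold constant threshold \eqn{\bar t} (variants T and D).
#' @slot weight parent weight \eqn{w \in [0,1]} (variant W).
#' @slot childStrategy positive-children strategy used inside variant W:
#'   one of "T", "AT", "TF".
#' @slot atGrid candidate thresholds searched by the adaptive strategy.
#' @slot atMetric per-term metric maximized by the adaptive strategy
#'   (only "F" — the F-score — is implemented).
#'
#' @seealso [tprConfig()], [tprCorrect()]
#' @export
setClass("TPRConfig",
    slots = c(
        variant       = "character",
        threshold     = "numeric",
        weight        = "numeric",
        childStrategy = "character",
        atGrid        = "numeric",
        atMetric      = "character"
    )
)

setValidity("TPRConfig", function(object) {
    msg <- character(0)
    if (!object@variant %in% c("T", "AT", "TF", "W", "D"))
        msg <- c(msg, "variant must be one of T, AT, TF, W, D")
    if (object@variant %in% c("T", "D")) {
        if (length(object@threshold) != 1L ||
            object@threshold <= 0 || object@threshold >= 1)
            msg <- c(msg, "variant T/D requires a constant threshold in (0,1)")
    }
    if (object@variant == "W") {
        if (length(object@weight) != 1L ||
            object@weight < 0 || object@weight > 1)
            msg <- c(msg, "variant W requires a weight in [0,1]")
        if (!object@childStrategy %in% c("T", "AT", "TF"))
            msg <- c(msg, "childStrategy must be one of T, AT, TF")
        if (object@childStrategy == "T" &&
            (length(object@threshold) != 1L ||
             object@threshold <= 0 || object@threshold >= 1))
            msg <- c(msg, "childStrategy T requires a constant threshold in (0,1)")
    }
    if (object@variant == "AT" || (object@variant == "W" && object@childStrategy == "AT")) {
        if (length(object@atGrid) < 1L || any(object@atGrid < 0 | object@atGrid > 1))
            msg <- c(msg, "atGrid must be a nonempty vector within [0,1]")
    }
    if (!identical(object@atMetric, "F"))
        msg <- c(msg, "only the F-score adaptive metric is implemented")
    if (length(msg) > 0L) msg else TRUE
})

#' EvaluationReport: gene-centric and term-centric performance summary
#'
#' @slot perTerm data.frame with columns \code{term}, \code{auroc},
#'   \code{auprc}; single-class terms carry \code{NA} and are excluded
#'   from the summary means.
#' @slot perGene data.frame with columns \code{gene}, \code{precision},
#'   \code{recall}, \code{f} evaluated at the Fmax threshold \eqn{\tau^*}.
#' @slot summary named numeric vector: \code{meanAUROC}, \code{meanAUPRC},
#'   \code{fmax}, \code{precision}, \code{recall}, \code{tauStar}.
#'
#' @seealso [evaluateScores()]
#' @export
setClass("EvaluationReport",
    slots = c(
        perTerm = "data.frame",
        perGene = "data.frame",
        summary = "numeric"
    )
)

setValidity("EvaluationReport", function(object) {
    need <- c("meanAUROC", "meanAUPRC", "fmax", "precision", "recall", "tauStar")
    if (!all(need %in% names(object@summary)))
        return(paste("summary must contain:", paste(need, collapse = ", ")))
    ok <- object@summary[setdiff(need, "tauStar")]
    ok <- ok[!is.na(ok)]
    if (any(ok < -1e-12 | ok > 1 + 1e-12))
        return("summary metric values must lie in [0,1]")
    TRUE
})
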