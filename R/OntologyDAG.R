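#' Construct an OntologyDAG from a parent-child edge list
#'
#' Builds and validates the ontology graph. If the edge list has several
#' source roots (terms with no incoming edge), a virtual root is inserted
#' and connected to each of them so that downstream per-level algorithms
#' always see a single root; the virtual root is removed again from
#' user-facing score and annotation outputs.
#'
#' @param edges two-column matrix or data.frame of character term ids,
#'   first column parent, second column child. May have zero rows for a
#'   single-term ontology (then \code{terms} must be given).
#' @param terms optional character vector of term ids; defaults to the
#'   ids appearing in \code{edges}. Ids not covered by edges are only
#'   allowed when they form the whole (single-term) ontology.
#' @param altIdMap named character vector mapping alternate ids to
#'   primary term ids.
#' @param virtualRootId id used for the inserted virtual root.
#' @return a validated [OntologyDAG-class] object.
#' @examples
#' dag <- OntologyDAG(rbind(c("root", "a"), c("a", "b")))
#' dagRoot(dag)
#' @export
OntologyDAG <- function(edges, terms = NULL, altIdMap = character(0),
                        virtualRootId = "VIRTUAL:ROOT") {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.null(edges) || length(edges) == 0L)
        edges <- matrix(character(0), ncol = 2L)
    storage.mode(edges) <- "character"
    if (nrow(edges) > 0L && ncol(edges) != 2L)
        stop("edges must have exactly two columns (parent, child)")
    edges <- unique(edges)
    colnames(edges) <- c("parent", "child")
    if (is.null(terms)) terms <- unique(as.vector(edges))
    terms <- unique(as.character(terms))
    if (length(terms) == 0L) stop("ontology must contain at least one term")
    unknown <- setdiff(as.vector(edges), terms)
    if (length(unknown) > 0L)
        stop("edge endpoint(s) not in term set: ", paste(unknown, collapse = ", "))

    roots <- setdiff(terms, edges[, "child"])
    if (length(roots) == 0L)
        stop("no root found: every term has an incoming edge (cycle?)")
    virtualRoot <- character(0)
    if (length(roots) > 1L) {
        if (virtualRootId %in% terms)
            stop("virtual root id '", virtualRootId, "' collides with a term id")
        edges <- rbind(edges, cbind(parent = virtualRootId, child = roots))
        terms <- c(virtualRootId, terms)
        virtualRoot <- virtualRootId
        roots <- virtualRootId
    }

    parents <- .adjacencyList(edges[, "child"], edges[, "parent"], terms)
    children <- .adjacencyList(edges[, "parent"], edges[, "child"], terms)

    if (length(altIdMap) > 0L) {
        altIdMap <- vapply(altIdMap, as.character, character(1))
        bad <- setdiff(altIdMap, terms)
        if (length(bad) > 0L)
            stop("altIdMap points at unknown term(s): ", paste(bad, collapse = ", "))
    } else {
        altIdMap <- stats::setNames(character(0), character(0))
    }

    obj <- new("OntologyDAG", terms = terms, edges = edges, root = roots,
               altIdMap = altIdMap, parents = parents, children = children,
               virtualRoot = virtualRoot)
    methods::validObject(obj)
    obj
}

.adjacencyList <- function(key, value, terms) {
    out <- split(value, factor(key, levels = terms))
    lapply(out, as.character)
}

## igraph view of the DAG; isolated vertices (single-term ontology) kept.
.dagIgraph <- function(dag) {
    igraph::graph_from_data_frame(
        as.data.frame(dag@edges, stringsAsFactors = FALSE),
        directed = TRUE,
        vertices = data.frame(name = dag@terms, stringsAsFactors = FALSE))
}

## Locate one directed cycle by iterative DFS over a children list;
## used only to produce an informative validity error.
.findCycle <- function(children) {
    color <- stats::setNames(rep.int(0L, length(children)), names(children))
    stackTrace <- character(0)
    found <- NULL
    visit <- function(v) {
        if (!is.null(found)) return()
        color[[v]] <<- 1L
        stackTrace <<- c(stackTrace, v)
        for (w in children[[v]]) {
            if (!is.null(found)) return()
            if (color[[w]] == 1L) {
                i <- match(w, stackTrace)
                found <<- c(stackTrace[i:length(stackTrace)], w)
                return()
            }
            if (color[[w]] == 0L) visit(w)
        }
        color[[v]] <<- 2L
        stackTrace <<- stackTrace[-length(stackTrace)]
    }
    for (v in names(children)) {
        if (color[[v]] == 0L) visit(v)
        if (!is.null(found)) break
    }
    found
}

#' @describeIn OntologyDAG-accessors term identifiers (virtual root included)
#' @export
dagTerms <- function(dag) dag@terms

#' Accessors for OntologyDAG objects
#'
#' @param dag an [OntologyDAG-class] object.
#' @param term a term id (for the single-term accessors), or \code{NULL}
#'   to return the full named list.
#' @name OntologyDAG-accessors
NULL

#' @describeIn OntologyDAG-accessors the root term id
#' @export
dagRoot <- function(dag) dag@root

#' @describeIn OntologyDAG-accessors parent-child edge matrix
#' @export
dagEdges <- function(dag) dag@edges

#' @describeIn OntologyDAG-accessors alternate-id to primary-id map
#' @export
altIdMap <- function(dag) dag@altIdMap

#' @describeIn OntologyDAG-accessors parents of one term, or named list of all
#' @export
dagParents <- function(dag, term = NULL) {
    if (is.null(term)) dag@parents else dag@parents[[term]]
}

#' @describeIn OntologyDAG-accessors children of one term, or named list of all
#' @export
dagChildren <- function(dag, term = NULL) {
    if (is.null(term)) dag@children else dag@children[[term]]
}

#' @describeIn OntologyDAG-accessors terms with no children
#' @export
dagLeaves <- function(dag) {
    dag@terms[vapply(dag@children[dag@terms], length, 1L) == 0L]
}

#' @describeIn OntologyDAG-accessors proper ancestors of a term
#' @export
dagAncestors <- function(dag, term) {
    g <- .dagIgraph(dag)
    setdiff(igraph::subcomponent(g, term, mode = "in")$name, term)
}

#' @describeIn OntologyDAG-accessors proper descendants of a term
#' @export
dagDescendants <- function(dag, term) {
    g <- .dagIgraph(dag)
    setdiff(igraph::subcomponent(g, term, mode = "out")$name, term)
}

## Proper-ancestor sets for every term at once, via one topological sweep.
.ancestorSets <- function(dag) {
    lev <- computeLevels(dag)
    ord <- names(sort(lev))
    anc <- vector("list", length(dag@terms))
    names(anc) <- dag@terms
    for (v in ord) {
        ps <- dag@parents[[v]]
        anc[[v]] <- if (length(ps) == 0L) character(0) else
            unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }
    anc
}

## Proper-descendant sets for every term (reverse topological sweep).
.descendantSets <- function(dag) {
    lev <- computeLevels(dag)
    ord <- names(sort(lev, decreasing = TRUE))
    des <- vector("list", length(dag@terms))
    names(des) <- dag@terms
    for (v in ord) {
        cs <- dag@children[[v]]
        des[[v]] <- if (length(cs) == 0L) character(0) else
            unique(c(cs, unlist(des[cs], use.names = FALSE)))
    }
    des
}

#' @importFrom methods show
setMethod("show", "OntologyDAG", function(object) {
    cat("OntologyDAG with", length(object@terms), "terms and",
        nrow(object@edges), "edges\n")
    cat("  root:", object@root,
        if (length(object@virtualRoot) > 0L) "(virtual)" else "", "\n")
    lv <- computeLevels(object)
    cat("  depth (max level):", max(lv), "\n")
    cat("  leaves:", sum(vapply(object@children, length, 1L) == 0L), "\n")
    if (length(object@altIdMap) > 0L)
        cat("  alternate ids mapped:", length(object@altIdMap), "\n")
    invisible(NULL)
})
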