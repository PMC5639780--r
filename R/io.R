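#' Read an ontology from a TSV parent-child edge list
#'
#' Two tab-separated columns, \code{parent<TAB>child}, no header.
#'
#' @param file path to the edge-list file.
#' @param ... passed on to [OntologyDAG()] (e.g. \code{altIdMap}).
#' @return an [OntologyDAG-class] object.
#' @export
readEdgeList <- function(file, ...) {
    df <- utils::read.table(file, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    if (ncol(df) != 2L)
        stop("edge list must have exactly two columns: ", file)
    OntologyDAG(as.matrix(df), ...)
}

#' Write an ontology's edges as a TSV edge list
#'
#' @param dag an [OntologyDAG-class] object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeEdgeList <- function(dag, file) {
    utils::write.table(dag@edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read gene-term annotation pairs
#'
#' TSV with two columns \code{gene<TAB>term}, one pair per line, no header.
#'
#' @param file path.
#' @return data.frame with character columns \code{gene} and \code{term}.
#' @export
readAnnotationPairs <- function(file) {
    df <- utils::read.table(file, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    if (ncol(df) != 2L)
        stop("annotation file must have exactly two columns: ", file)
    names(df) <- c("gene", "term")
    df
}

#' Write a binary annotation matrix as gene-term pairs
#'
#' @param annotations binary gene x term matrix with dimnames.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeAnnotationPairs <- function(annotations, file) {
    idx <- which(annotations == 1, arr.ind = TRUE)
    df <- data.frame(gene = rownames(annotations)[idx[, 1L]],
                     term = colnames(annotations)[idx[, 2L]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$gene, df$term), , drop = FALSE]
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a gene x term score matrix
#'
#' TSV with a header row; the first column is named \code{gene}, the
#' remaining column names are term ids, entries are numeric scores.
#'
#' @param file path.
#' @return numeric matrix with gene rownames and term colnames.
#' @export
readScoreMatrix <- function(file) {
    header <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || header[1L] != "gene")
        stop("malformed score matrix (first header field must be 'gene'): ",
             file, " line 1")
    df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                            quote = "", comment.char = "",
                            colClasses = c("character", rep("numeric", length(header) - 1L)))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
}

#' Write a gene x term score matrix
#'
#' Values are printed with 10 significant digits so that write/read
#' round-trips are reproducible.
#'
#' @param scores numeric matrix with gene rownames and term colnames.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeScoreMatrix <- function(scores, file) {
    df <- data.frame(gene = rownames(scores),
                     signif(scores, 10L),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a weighted gene network from a TSV edge list
#'
#' Three columns \code{geneA<TAB>geneB<TAB>weight}, no header. The
#' network is undirected: each edge is mirrored into a symmetric
#' adjacency matrix. Duplicate (unordered) edges are averaged with a
#' warning; the diagonal defaults to zero.
#'
#' @param file path.
#' @param genes optional character vector fixing the gene universe and
#'   ordering; defaults to the genes seen in the file.
#' @return symmetric numeric matrix with gene dimnames.
#' @export
readNetwork <- function(file, genes = NULL) {
    df <- utils::read.table(file, sep = "\t", header = FALSE, quote = "",
                            comment.char = "",
                            colClasses = c("character", "character", "numeric"))
    names(df) <- c("a", "b", "w")
    key <- paste(pmin(df$a, df$b), pmax(df$a, df$b), sep = "\r")
    if (anyDuplicated(key)) {
        warning("duplicate edges averaged in ", file)
        df <- do.call(rbind, lapply(split(df, key), function(d)
            data.frame(a = d$a[1L], b = d$b[1L], w = mean(d$w),
                       stringsAsFactors = FALSE)))
    }
    if (is.null(genes)) genes <- sort(unique(c(df$a, df$b)))
    w <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
    w[cbind(df$a, df$b)] <- df$w
    w[cbind(df$b, df$a)] <- df$w
    w
}

#' Write a gene network as a TSV edge list
#'
#' Emits each unordered pair with nonzero weight once, 10 significant
#' digits, no header.
#'
#' @param network symmetric numeric matrix with gene dimnames.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeNetwork <- function(network, file) {
    idx <- which(upper.tri(network) & network != 0, arr.ind = TRUE)
    df <- data.frame(a = rownames(network)[idx[, 1L]],
                     b = colnames(network)[idx[, 2L]],
                     w = signif(network[idx], 10L),
                     stringsAsFactors = FALSE)
    df <- df[order(df$a, df$b), , drop = FALSE]
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}
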