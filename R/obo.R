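#' Parse an OBO ontology file into an OntologyDAG
#'
#' Reads the standard \code{[Term]} stanza subset of the OBO flat-file
#' format: \code{id}, \code{name}, \code{alt_id}, \code{is_a} and
#' \code{is_obsolete}. Only \code{is_a} relationships become edges
#' (\code{part_of} and other relationship lines are ignored); obsolete
#' terms are dropped entirely. \code{alt_id} lines populate the
#' alternate-id map used to remap annotations made against superseded
#' term identifiers.
#'
#' @param file path to an OBO document.
#' @return an [OntologyDAG-class] object.
#' @seealso [writeOBO()] for the matching writer.
#' @export
parseOBO <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("\\s*!.*$", "", lines)        # trailing comments
    lines <- trimws(lines)

    stanzaStart <- grep("^\\[", lines)
    if (length(stanzaStart) == 0L) stop("no stanzas found in OBO file: ", file)
    stanzaEnd <- c(stanzaStart[-1L] - 1L, length(lines))
    isTerm <- lines[stanzaStart] == "[Term]"

    ids <- character(0); edges <- NULL; altFrom <- character(0); altTo <- character(0)
    for (k in which(isTerm)) {
        body <- lines[seq.int(stanzaStart[k] + 1L, stanzaEnd[k])]
        body <- body[nzchar(body)]
        fields <- sub(":.*$", "", body)
        values <- trimws(sub("^[^:]+:", "", body))
        id <- values[fields == "id"][1L]
        if (is.na(id)) stop("[Term] stanza without an id in ", file)
        obsolete <- any(fields == "is_obsolete" & tolower(values) == "true")
        if (obsolete) next
        ids <- c(ids, id)
        isa <- values[fields == "is_a"]
        isa <- trimws(sub("\\{.*\\}$", "", isa))   # trailing qualifiers
        if (length(isa) > 0L)
            edges <- rbind(edges, cbind(parent = isa, child = rep(id, length(isa))))
        alt <- values[fields == "alt_id"]
        if (length(alt) > 0L) {
            altFrom <- c(altFrom, alt)
            altTo <- c(altTo, rep(id, length(alt)))
        }
    }
    if (length(ids) == 0L) stop("no non-obsolete [Term] stanzas in ", file)
    if (!is.null(edges)) {
        missing <- setdiff(edges[, "parent"], ids)
        if (length(missing) > 0L)
            stop("is_a target(s) absent from ontology: ",
                 paste(missing, collapse = ", "))
    }
    OntologyDAG(edges, terms = ids,
                altIdMap = stats::setNames(altTo, altFrom))
}

#' Write an OntologyDAG as a minimal OBO document
#'
#' Emits one \code{[Term]} stanza per term with its \code{is_a} parents
#' and any alternate ids. The virtual root (if present) is written like
#' any other term so that the file round-trips through [parseOBO()].
#'
#' @param dag an [OntologyDAG-class] object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeOBO <- function(dag, file) {
    con <- file(file, open = "wt")
    on.exit(close(con))
    writeLines(c("format-version: 1.2", ""), con)
    altByTerm <- split(names(dag@altIdMap), dag@altIdMap)
    for (t in dag@terms) {
        out <- c("[Term]", paste0("id: ", t), paste0("name: ", t))
        alt <- altByTerm[[t]]
        if (!is.null(alt)) out <- c(out, paste0("alt_id: ", alt))
        ps <- dag@parents[[t]]
        if (length(ps) > 0L) out <- c(out, paste0("is_a: ", ps))
        writeLines(c(out, ""), con)
    }
    invisible(file)
}
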