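# Shared fixtures, built in code.

chainDag <- function() OntologyDAG(rbind(c("root", "a"), c("a", "b")))

# Diamond with a shortcut edge: root -> a -> b -> c, root -> c.
# Max-distance levels put c at 3; min-distance puts it at 1.
shortcutDag <- function() OntologyDAG(rbind(
    c("root", "a"), c("a", "b"), c("b", "c"), c("root", "c")))

# A random DAG with annotations and noisy flat scores.
randomInstance <- function(seed, nTerms = 50, nGenes = 20, nLevels = 5,
                           edgeDensity = 0.08, sigma = 0.3, mean = 3) {
    dag <- generateDAG(nTerms, nLevels = nLevels, edgeDensity = edgeDensity,
                       seed = seed)
    ann <- generateAnnotations(dag, nGenes, mean, seed = seed + 1000L)
    flat <- generateFlatScores(ann, sigma = sigma, seed = seed + 2000L)
    list(dag = dag, ann = ann, flat = flat)
}

# Independent ancestor sets computed through igraph, used as oracle.
oracleAncestors <- function(dag, term) {
    g <- igraph::graph_from_data_frame(
        as.data.frame(dagEdges(dag), stringsAsFactors = FALSE),
        directed = TRUE,
        vertices = data.frame(name = dagTerms(dag)))
    setdiff(igraph::subcomponent(g, term, mode = "in")$name, term)
}

# Exhaustive longest-path lengths by DFS path enumeration (small DAGs).
oracleLongestPath <- function(dag) {
    children <- dagChildren(dag)
    best <- stats::setNames(rep(-Inf, length(dagTerms(dag))), dagTerms(dag))
    walk <- function(v, len) {
        if (len > best[[v]]) best[[v]] <<- len
        for (w in children[[v]]) walk(w, len + 1L)
    }
    walk(dagRoot(dag), 0L)
    best
}
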