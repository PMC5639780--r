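test_that("OBO parsing builds the DAG, maps alt ids, drops obsolete terms", {
    obo <- tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: HP:0000001", "name: All", "",
        "[Term]", "id: HP:0000002", "name: A", "alt_id: HP:0000099",
        "is_a: HP:0000001 ! All", "",
        "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002", "",
        "[Term]", "id: HP:0000666", "name: gone", "is_obsolete: true", "",
        "[Typedef]", "id: part_of", ""), obo)
    dag <- parseOBO(obo)
    expect_setequal(dagTerms(dag), c("HP:0000001", "HP:0000002", "HP:0000003"))
    expect_equal(nrow(dagEdges(dag)), 2L)
    expect_equal(dagRoot(dag), "HP:0000001")
    expect_equal(unname(altIdMap(dag)["HP:0000099"]), "HP:0000002")
})

test_that("OBO parsing rejects broken ontologies", {
    missingParent <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "id: X", "is_a: NOT_THERE", ""), missingParent)
    expect_error(parseOBO(missingParent), "NOT_THERE")

    cyc <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "id: A", "is_a: B", "",
                 "[Term]", "id: B", "is_a: A", ""), cyc)
    expect_error(parseOBO(cyc), "cycle")
})

test_that("a generated ontology round-trips through write-then-parse", {
    dag <- generateDAG(50, nLevels = 5, edgeDensity = 0.1, seed = 11)
    f <- tempfile(fileext = ".obo")
    writeOBO(dag, f)
    back <- parseOBO(f)
    canon <- function(e) paste(e[, 1], e[, 2])
    expect_setequal(canon(dagEdges(back)), canon(dagEdges(dag)))
    expect_setequal(dagTerms(back), dagTerms(dag))

    f2 <- tempfile(fileext = ".tsv")
    writeEdgeList(dag, f2)
    back2 <- readEdgeList(f2)
    expect_setequal(canon(dagEdges(back2)), canon(dagEdges(dag)))
})

test_that("multi-root edge lists get a virtual root that is stripped from outputs", {
    dag <- OntologyDAG(rbind(c("r1", "a"), c("r2", "b")))
    expect_equal(dagRoot(dag), "VIRTUAL:ROOT")
    expect_true("VIRTUAL:ROOT" %in% dagTerms(dag))
    flat <- matrix(runif(8), 2, 4,
                   dimnames = list(c("g1", "g2"), c("r1", "a", "r2", "b")))
    corr <- htdCorrect(dag, flat)
    expect_setequal(colnames(corr), c("r1", "a", "r2", "b"))
    # the virtual root (score 1) must never cap a real root
    expect_equal(corr[, "r1"], flat[, "r1"])
    expect_equal(corr[, "r2"], flat[, "r2"])
})

test_that("levels are longest paths from the root", {
    expect_equal(computeLevels(chainDag()),
                 c(root = 0L, a = 1L, b = 2L))
    # max-distance beats the shortcut: c sits below b, not beside a
    dag <- shortcutDag()
    expect_equal(computeLevels(dag)[["c"]], 3L)
    expect_equal(computeLevels(dag, distance = "min")[["c"]], 1L)

    for (seed in c(3, 17)) {
        small <- generateDAG(12, nLevels = 4, edgeDensity = 0.3, seed = seed)
        expect_equal(computeLevels(small)[dagTerms(small)],
                     oracleLongestPath(small)[dagTerms(small)],
                     ignore_attr = FALSE)
    }
    big <- generateDAG(100, nLevels = 6, edgeDensity = 0.05, seed = 23)
    expect_equal(computeLevels(big)[dagTerms(big)],
                 oracleLongestPath(big)[dagTerms(big)])
    # every edge descends by at least one level
    lv <- computeLevels(big)
    e <- dagEdges(big)
    expect_true(all(lv[e[, "child"]] >= lv[e[, "parent"]] + 1L))
})

test_that("annotation propagation closes over ancestors and is idempotent", {
    dag <- chainDag()
    raw <- data.frame(gene = "g", term = "b")
    lab <- propagateAnnotations(dag, raw)
    expect_equal(lab["g", c("root", "a", "b")], c(root = 1L, a = 1L, b = 1L))
    expect_equal(propagateAnnotations(dag, lab), lab)

    # unknown terms skipped with a warning; alt ids remapped
    dag2 <- OntologyDAG(rbind(c("root", "a")),
                        altIdMap = c(old_a = "a"))
    expect_warning(
        lab2 <- propagateAnnotations(
            dag2, data.frame(gene = c("g", "g"), term = c("old_a", "nope"))),
        "1 annotation pair")
    expect_equal(lab2["g", "a"], 1L)
})

test_that("propagation matches a per-gene reverse-BFS oracle on random DAGs", {
    inst <- randomInstance(5, nTerms = 40, nGenes = 15)
    pool <- setdiff(dagTerms(inst$dag), dagRoot(inst$dag))
    set.seed(99)
    raw <- data.frame(gene = sample(sprintf("g%02d", 1:15), 60, replace = TRUE),
                      term = sample(pool, 60, replace = TRUE))
    lab <- propagateAnnotations(inst$dag, raw)
    for (g in unique(raw$gene)) {
        seeds <- unique(raw$term[raw$gene == g])
        closed <- unique(c(seeds, unlist(lapply(seeds, function(t)
            oracleAncestors(inst$dag, t)))))
        expect_setequal(colnames(lab)[lab[g, ] == 1], closed)
    }
    # monotone: adding a pair never removes a closed pair
    lab2 <- propagateAnnotations(
        inst$dag, rbind(raw, data.frame(gene = raw$gene[1], term = pool[1])))
    expect_true(all(lab2[rownames(lab), colnames(lab)] >= lab))
})

test_that("pruning drops rare terms, re-wires to surviving ancestors, keeps root", {
    dag <- chainDag()
    ann <- matrix(0L, 12, 3, dimnames = list(sprintf("g%02d", 1:12),
                                             c("root", "a", "b")))
    ann[, "root"] <- 1L; ann[, "a"] <- 1L; ann[1:3, "b"] <- 1L
    pr <- pruneTerms(dag, ann, minCount = 10)
    expect_setequal(dagTerms(pr$dag), c("root", "a"))
    expect_equal(colnames(pr$annotations), c("root", "a"))

    # minCount = 0 is the identity
    id <- pruneTerms(dag, ann, minCount = 0)
    expect_setequal(dagTerms(id$dag), dagTerms(dag))
    expect_equal(dagEdges(id$dag), dagEdges(dag))
    expect_equal(id$annotations, ann)

    # re-wiring: pruning the middle of a chain connects root to the leaf
    ann2 <- ann; ann2[, "a"] <- 0L; ann2[, "b"] <- 1L
    pr2 <- pruneTerms(dag, ann2, minCount = 5)
    expect_setequal(dagTerms(pr2$dag), c("root", "b"))
    expect_equal(unname(dagParents(pr2$dag, "b")), "root")
})

test_that("pruning matches the count-and-filter oracle and preserves reachability", {
    inst <- randomInstance(7, nTerms = 60, nGenes = 30, mean = 4)
    minCount <- 5
    pr <- pruneTerms(inst$dag, inst$ann, minCount)
    counts <- colSums(inst$ann)
    expectSurvive <- union(names(counts)[counts >= minCount], dagRoot(inst$dag))
    expect_setequal(dagTerms(pr$dag), expectSurvive)
    expect_true(all(colSums(pr$annotations) >= minCount |
                    colnames(pr$annotations) == dagRoot(pr$dag)))
    # validity of the pruned object implies reachability from the root
    expect_true(methods::validObject(pr$dag))
})

test_that("consistency checking finds exactly the violating triples", {
    dag <- OntologyDAG(rbind(c("p", "c")))
    scores <- matrix(c(0.3, 0.7), 1, dimnames = list("g", c("p", "c")))
    v <- checkConsistency(dag, scores)
    expect_equal(nrow(v), 1L)
    expect_equal(v$gene, "g"); expect_equal(v$parent, "p"); expect_equal(v$child, "c")

    inst <- randomInstance(13)
    v2 <- checkConsistency(inst$dag, inst$flat)
    # exhaustive per-edge scan oracle
    e <- dagEdges(inst$dag)
    expected <- 0L
    for (k in seq_len(nrow(e)))
        expected <- expected + sum(inst$flat[, e[k, "child"]] -
                                   inst$flat[, e[k, "parent"]] > 1e-9)
    expect_equal(nrow(v2), expected)
    expect_true(expected > 0)  # noisy flat scores do violate the rule
})
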