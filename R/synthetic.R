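#' Generate a layered random ontology DAG
#'
#' Terms are partitioned over \code{nLevels} layers with a single root
#' on layer 0. Every non-root term receives one guaranteed parent from
#' the layer directly above (so the layer index equals the
#' maximum-distance level) plus each remaining shallower term as an
#' extra parent independently with probability \code{edgeDensity}.
#' Output is a pure function of the arguments when \code{seed} is given.
#'
#' @param nTerms total number of terms (>= 1).
#' @param nLevels number of layers including the root layer (>= 2 unless
#'   \code{nTerms == 1}).
#' @param edgeDensity probability of each optional extra parent edge.
#' @param seed optional integer seed.
#' @return an [OntologyDAG-class] object.
#' @export
generateDAG <- function(nTerms, nLevels = 4L, edgeDensity = 0.05,
                        seed = NULL) {
    if (nTerms < 1L) stop("nTerms must be positive")
    ids <- sprintf("T%04d", seq_len(nTerms))
    if (nTerms == 1L) return(OntologyDAG(NULL, terms = ids))
    .withSeed(seed, {
        nLevels <- min(nLevels, nTerms)
        if (nLevels < 2L) stop("nLevels must be >= 2")
        # one root; every other layer nonempty
        layer <- integer(nTerms)
        layer[seq_len(nLevels)] <- seq_len(nLevels) - 1L
        if (nTerms > nLevels)
            layer[(nLevels + 1L):nTerms] <-
                sample(nLevels - 1L, nTerms - nLevels, replace = TRUE)
        layer <- c(0L, sort(layer[-1L]))  # ids ordered by depth
        edges <- vector("list", nTerms)
        for (k in which(layer > 0L)) {
            above <- ids[layer == layer[k] - 1L]
            shallower <- ids[layer < layer[k]]
            primary <- if (length(above) == 1L) above else sample(above, 1L)
            extra <- setdiff(shallower, primary)
            extra <- extra[stats::runif(length(extra)) < edgeDensity]
            edges[[k]] <- cbind(parent = c(primary, extra),
                                child = ids[k])
        }
        OntologyDAG(do.call(rbind, edges), terms = ids)
    })
}

#' Generate true-path-consistent gene annotations
#'
#' Each gene draws a Poisson number of seed terms, sampled among the
#' non-root terms with probability proportional to \code{level + 1} (a
#' depth bias, so that specific terms are annotated often enough to
#' exercise the bottom-up ensemble logic), and the seed set is closed
#' under ancestors. Every gene is annotated to the root; genes that drew
#' no seed term carry the root annotation only.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param nGenes number of genes.
#' @param meanAnnotations Poisson mean of the per-gene seed-term count.
#' @param seed optional integer seed.
#' @return binary gene x term matrix satisfying the closure invariant.
#' @export
generateAnnotations <- function(dag, nGenes, meanAnnotations = 3,
                                seed = NULL) {
    .withSeed(seed, {
        genes <- sprintf("G%04d", seq_len(nGenes))
        lev <- computeLevels(dag)
        pool <- setdiff(dag@terms, c(dag@root, dag@virtualRoot))
        prob <- (lev[pool] + 1)
        pairs <- lapply(genes, function(g) {
            n <- min(stats::rpois(1L, meanAnnotations), length(pool))
            if (n == 0L || length(pool) == 0L) return(NULL)
            data.frame(gene = g,
                       term = sample(pool, n, prob = prob),
                       stringsAsFactors = FALSE)
        })
        pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
        labels <- if (is.null(pairs)) {
            keep <- setdiff(dag@terms, dag@virtualRoot)
            matrix(0L, nGenes, length(keep), dimnames = list(genes, keep))
        } else {
            propagateAnnotations(dag, pairs, genes = genes)
        }
        labels[, dag@root] <- 1L
        labels
    })
}

#' Generate noisy flat scores correlated with the labels
#'
#' Gaussian model: \code{clip(label + N(0, sigma), 0, 1)}; flip model:
#' with probability \code{flipProb} an entry is replaced by a uniform
#' draw. At \code{sigma = 0} (or \code{flipProb = 0}) the scores equal
#' the labels exactly. Gaussian noise on a true-path-consistent label
#' matrix almost surely produces parent/child inconsistencies, which is
#' precisely the problem the hierarchical correction exists to repair.
#'
#' @param annotations binary gene x term label matrix.
#' @param noise \code{"gaussian"} or \code{"flip"}.
#' @param sigma Gaussian noise standard deviation.
#' @param flipProb per-entry replacement probability (flip model).
#' @param seed optional integer seed.
#' @return numeric score matrix in [0,1] with the labels' dimnames.
#' @export
generateFlatScores <- function(annotations, noise = c("gaussian", "flip"),
                               sigma = 0.3, flipProb = 0.1, seed = NULL) {
    noise <- match.arg(noise)
    .withSeed(seed, {
        m <- annotations * 1.0
        if (noise == "gaussian") {
            if (sigma < 0) stop("sigma must be non-negative")
            if (sigma > 0)
                m <- m + stats::rnorm(length(m), sd = sigma)
            m <- pmin(pmax(m, 0), 1)
        } else {
            if (flipProb < 0 || flipProb > 1) stop("flipProb must be in [0,1]")
            hit <- stats::runif(length(m)) < flipProb
            m[hit] <- stats::runif(sum(hit))
        }
        dim(m) <- dim(annotations)
        dimnames(m) <- dimnames(annotations)
        m
    })
}

#' Scaled-down hold-out comparison of flat vs hierarchically corrected scores
#'
#' Splits the genes into a training and a test fraction, fits every
#' trainable ingredient (adaptive thresholds, the TPR-W weight) on the
#' training genes only, corrects the test genes' flat scores, and
#' returns paired evaluation reports for the flat and the corrected
#' test scores together with their consistency-violation counts.
#'
#' @param dag an [OntologyDAG-class] object.
#' @param annotations binary gene x term matrix (true-path closed).
#' @param flat numeric gene x term flat score matrix.
#' @param trainFraction fraction of genes used for training, in (0,1).
#' @param method \code{"htd"} or a TPR variant (\code{"tpr-t"},
#'   \code{"tpr-at"}, \code{"tpr-tf"}, \code{"tpr-w"}, \code{"tpr-d"}).
#' @param weight TPR-W weight; ignored when \code{weightGrid} is given.
#' @param weightGrid optional grid: the weight is then tuned by internal
#'   cross-validation ([tuneWeight()]) on the training genes.
#' @param threshold,atGrid,childStrategy passed to [tprConfig()].
#' @param nFolds internal CV folds for weight tuning.
#' @param tauGrid threshold grid for the evaluation metrics.
#' @param seed optional integer seed (drives the split and any tuning).
#' @return list with elements \code{flat} and \code{corrected}
#'   ([EvaluationReport-class]), \code{violationsFlat},
#'   \code{violationsCorrected}, \code{weight} (selected or fixed, TPR-W
#'   only), and \code{split} (train/test gene ids).
#' @export
holdoutExperiment <- function(dag, annotations, flat, trainFraction = 0.7,
                              method = "tpr-w", weight = 0.5,
                              weightGrid = NULL, threshold = 0.5,
                              atGrid = seq(0.05, 0.95, by = 0.05),
                              childStrategy = "TF", nFolds = 5L,
                              tauGrid = seq(0, 1, by = 0.01), seed = NULL) {
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must be in (0,1)")
    .withSeed(seed, {
        genes <- rownames(flat)
        nTrain <- round(trainFraction * length(genes))
        if (nTrain < 1L || nTrain >= length(genes))
            stop("degenerate train/test split")
        train <- sample(genes, nTrain)
        test <- setdiff(genes, train)
        annTr <- annotations[train, , drop = FALSE]
        annTe <- annotations[test, , drop = FALSE]
        flTr <- flat[train, , drop = FALSE]
        flTe <- flat[test, , drop = FALSE]
        if (sum(annTe[, setdiff(colnames(annTe), dag@root)]) == 0L)
            stop("degenerate split: no annotated test gene")

        usedWeight <- NULL
        corrected <- switch(method,
            "htd" = htdCorrect(dag, flTe),
            "tpr-t" = tprCorrect(dag, flTe, tprConfig("T", threshold = threshold)),
            "tpr-tf" = tprCorrect(dag, flTe, tprConfig("TF")),
            "tpr-d" = tprCorrect(dag, flTe, tprConfig("D", threshold = threshold)),
            "tpr-at" = tprCorrect(dag, flTe, tprConfig("AT", atGrid = atGrid),
                                  annotations = annTr, trainScores = flTr),
            "tpr-w" = {
                usedWeight <- if (!is.null(weightGrid) && length(weightGrid) > 1L)
                    as.numeric(tuneWeight(dag, flTr, annTr, weightGrid,
                                          nFolds = nFolds,
                                          childStrategy = childStrategy,
                                          threshold = threshold,
                                          atGrid = atGrid, tauGrid = tauGrid))
                else if (!is.null(weightGrid)) weightGrid[1L] else weight
                tprCorrect(dag, flTe,
                           tprConfig("W", weight = usedWeight,
                                     childStrategy = childStrategy,
                                     threshold = threshold, atGrid = atGrid),
                           annotations = annTr, trainScores = flTr)
            },
            stop("unknown method: ", method))

        list(flat = evaluateScores(flTe, annTe, dag = dag, tauGrid = tauGrid),
             corrected = evaluateScores(corrected, annTe, dag = dag,
                                        tauGrid = tauGrid),
             violationsFlat = nrow(checkConsistency(dag, flTe)),
             violationsCorrected = nrow(checkConsistency(dag, corrected)),
             weight = usedWeight,
             split = list(train = train, test = test))
    })
}

## Evaluate expr under a temporary RNG state seeded with `seed`;
## with seed = NULL the global RNG stream is used as-is.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}
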