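# hierDAG

Hierarchical ensemble correction of flat prediction scores over
DAG-structured ontologies.

## The problem

Predicting which ontology terms apply to a gene — for instance, which
Human Phenotype Ontology (HPO) abnormalities are associated with it — is
usually done one term at a time by independent ("flat") classifiers.
Independent scores routinely break the **true path rule**: a gene
annotated to a term is implicitly annotated to every ancestor of that
term, so a biologically meaningful score vector ŷ must satisfy

    for every term i and every parent j of i:  y_j ≥ y_i

Flat learners know nothing of the hierarchy and happily score
*Hyperplasia of metatarsal bones* above *Abnormality of the metatarsal
bones*. `hierDAG` post-processes any flat gene × term score matrix into
a provably consistent one, usually improving accuracy along the way.

## The methods

Both engines first assign every term its **level** ψ(i), the *longest*
path length from the root (shortest paths break the consistency
guarantee — the package proves this to you in a test).

**HTD-DAG** (hierarchical top-down) visits terms by increasing level and
caps each score by its parents:

    ȳ_i = min( ŷ_i, min_{j ∈ par(i)} ȳ_j )

equivalently ȳ_i is the minimum flat score over the term and all its
ancestors.

**TPR-DAG** (true path rule) adds a prior bottom-up pass from the
deepest level to the root, averaging each term's flat score with its
"positive" children φ_i:

    ȳ_i = (ŷ_i + Σ_{j ∈ φ_i} ȳ_j) / (1 + |φ_i|)

followed by the HTD top-down pass, which restores consistency. Positive
children are chosen by a constant threshold (**TPR-T**), per-term
adaptive thresholds fitted on training annotations (**TPR-AT**), or
threshold-free — children outscoring the parent's own flat score
(**TPR-TF**). **TPR-W** balances parent and children with a weight
w ∈ [0,1] (w = 1 reduces exactly to HTD-DAG); **TPR-D** lets all
positive *descendants* vote, not just children.

Supporting modules: OBO parsing with alt-id remapping, annotation
propagation and minimum-count pruning, max/quantile score
normalization, Jaccard feature networks and unweighted-average network
integration, a kernel neighborhood flat scorer, CAFA-style evaluation
(gene-centric Fmax, term-centric AUROC/AUPRC), candidate-gene
nomination, and a synthetic-data generator.

## Worked example

```r
library(hierDAG)

dag  <- generateDAG(60, nLevels = 5, edgeDensity = 0.1, seed = 3)
ann  <- generateAnnotations(dag, 40, 3, seed = 4)   # true-path closed labels
flat <- generateFlatScores(ann, sigma = 0.3, seed = 5)

nrow(checkConsistency(dag, flat))
#> [1] 1728                      # noisy flat scores violate the hierarchy

corr <- tprCorrect(dag, flat, tprConfig("W", weight = 0.5))
nrow(checkConsistency(dag, corr))
#> [1] 0                         # guaranteed by construction

evaluateScores(flat, ann, dag = dag)
#> EvaluationReport: 60 terms, 38 genes
#>   mean AUROC 0.9899 | mean AUPRC 0.9706
#>   Fmax 0.9268 at tau* = 0.52 (Pr 0.8978, Rc 0.9577)
```

The report reads: ranking genes within each term, the flat scores reach
a mean AUROC of 0.99; ranking terms within each gene, the best
achievable hierarchical F-score (harmonic mean of gene-averaged
precision and recall, maximized over the score threshold τ) is 0.927 at
τ\* = 0.52. After correction the violations are gone and Fmax rises
(see below).

A shell interface over the same functions ships at
`inst/cli/hierdag.R`, with subcommands `simulate`, `correct`,
`evaluate`, `candidates` and `integrate`; every run writes a JSON
manifest with parameters, seed and input digests.

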