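---
title: "Hierarchical correction of ontology-term predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical correction of ontology-term predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierDAG)
```

## The model

An ontology such as the Human Phenotype Ontology is a directed acyclic
graph G = <V, E> whose vertices are terms and whose edges point from a
parent (more general) term to each of its children. Annotations obey
the *true path rule*: a gene annotated to a term is annotated to all of
the term's ancestors. A vector of per-term prediction scores
ŷ ∈ [0,1]^|V| for one gene is *consistent* when every parent scores at
least as high as each of its children; independent per-term classifiers
essentially never satisfy this.

`hierDAG` treats the flat learner as a black box and repairs its output.
Two engines are provided.

**Levels.** Both engines traverse the DAG level by level, where the
level ψ(i) of a term is the length of the *longest* directed path from
the root, computed by dynamic programming over a topological order.
Longest — not shortest — distances are load-bearing: with shortest-path
levels a deep term reachable through a shortcut edge is processed
before one of its parents, and the top-down pass can leave a
parent–child inversion behind. `computeLevels(dag, distance = "min")`
exists solely so that tests can demonstrate this failure on a diamond
with a shortcut edge; `htdCorrect()` refuses such level maps unless
explicitly overridden.

**HTD-DAG.** Visiting terms by increasing level,

ȳ_i = ŷ_i at the root, otherwise min(ŷ_i, min over parents j of ȳ_j).

By induction this equals the minimum flat score over {i} ∪ anc(i), which
is the closed form the test suite checks exactly. Consequences that are
also tested as properties: the output is always consistent, the
operation is idempotent, and an already-consistent matrix passes through
unchanged.

**TPR-DAG.** A bottom-up pass (levels ξ down to 0) first lets each
term's "positive" children φ_i raise it:

ȳ_i = (ŷ_i + Σ_{j ∈ φ_i} ȳ_j) / (1 + |φ_i|)

Only positive children vote because the true path rule is asymmetric: a
child's *absence* of annotation says nothing about the parent. The
bottom-up pass propagates evidence but does not enforce consistency, so
it is followed by the full HTD top-down pass. Positive-children rules
(all comparisons strict; a child exactly at its threshold is negative,
the literal reading of the definitions):

* **T** — fixed threshold t̄ (default 0.5, natural when scores are
  probabilities);
* **AT** — per-term thresholds t*_j maximizing the training F-score
  over a grid;
* **TF** — children exceeding the parent's own flat score, i.e. exactly
  those able to raise it;
* **W** — ȳ_i = w·ŷ_i + (1−w)/|φ_i| · Σ ȳ_j with w ∈ [0,1], children
  chosen by one of the rules above (default TF, the best-performing
  combination in the literature this package follows);
* **D** — like the base average but over positive *descendants*
  Δ_i = {j ∈ desc(i) | ȳ_j > t_j}, giving distant specific terms an
  undamped vote.

Tested guarantees: every variant produces consistent output in [0,1];
TPR-W with w = 1 is bit-identical to HTD-DAG (the weighted update
degenerates to the identity bottom-up); TPR-TF dominates HTD-DAG
entrywise, which implies its per-term sensitivity is at least HTD's at
every threshold.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `threshold` (t̄) | TPR-T/-D | 0.5 | midpoint of [0,1], the probability reading |
| `weight` (w) | TPR-W | 0.5, or tuned | w=1 ⇒ HTD; w=0 ⇒ children only |
| `atGrid` | TPR-AT | 0.05…0.95 step 0.05 | covers (0,1) without the degenerate ends |
| `tauGrid` | Fmax | 0…1 step 0.01 | the standard evaluation grid |
| `minCount` | pruning | caller's | terms with too few annotations cannot be assessed reliably |
| consistency `tol` | checker | 1e−9 | absorbs float noise from averaging |

The TPR-W weight is selected by internal cross-validation on training
genes only (`tuneWeight()`): because the correction of one gene never
reads another gene's scores, a fold's corrected matrix equals the
full-matrix correction restricted to that fold, and the CV is cheap.
Fold assignment comes from R's RNG, so runs are reproducible under
`set.seed()`.

### Design choices where the design was open

* **AT thresholds are fitted on flat training scores**, not partially
  corrected ones — they must exist before the bottom-up pass runs. The
  fit is a direct, deterministic grid search (smallest grid value on
  ties); terms with no positive training gene keep the largest grid
  value, so unsupported children cannot vote.
* **TPR-D thresholds** default to the constant t̄, the simplest faithful
  reading of the descendant rule.
* **TPR-W with an empty positive set** returns ŷ_i unchanged: the
  weighted formula divides by |φ_i|, and returning the flat score
  matches the base-average limit while avoiding systematic shrinkage of
  leaves.
* **Multiple roots** get a virtual root joined to every source root. Its
  score is pinned at 1 throughout both passes, so it can never cap a
  real root, and it is stripped from outputs — per-term results are
  unchanged relative to treating each component separately.
* **Pruning re-wiring**: terms below the annotation cut-off are
  contracted out (each removed term's parents are joined to its
  children), which connects every survivor to its nearest surviving
  ancestors and keeps `minCount = 0` an exact identity. A transitive
  reduction would instead also delete legitimate redundant edges that
  were present in the input ontology.
* **Evaluation conventions**: gene-centric prediction sets use
  score ≥ τ; genes with an empty prediction set are excluded from the
  precision average (the 0/0 case; counting them as zero is available
  behind a flag); the root is excluded from gene-centric metrics; the
  term-centric AUROC uses mean ranks, so ties contribute 1/2 and
  constant scores give exactly 0.5. Note that Fmax selects τ* a
  posteriori and is therefore an optimistic bound on any operating
  F-score. Ties at the candidate-selection top-k boundary are broken
  lexicographically by gene id so the top set is well defined.
* **Network integration** min-max normalizes each network over its
  observed weights before averaging; a constant-positive network maps
  to all-ones, a zero network stays zero.
* **Out-of-range flat scores are fatal**, never silently rescaled —
  rescaling changes the semantics of thresholds; `normalizeMax()` is
  the explicit opt-in.

## What the synthetic generator emulates — and what it does not

`generateDAG()` builds layered random DAGs: one root, every non-root
term gets a guaranteed parent in the layer directly above (so the layer
index *is* the longest-path level) plus extra shallower parents with
probability `edgeDensity`. `generateAnnotations()` seeds each gene with
a Poisson number of terms sampled with probability proportional to
level + 1 — the depth bias keeps leaves annotated often enough to
exercise the bottom-up logic, where uniform sampling would concentrate
annotations near the root and trivialize correction.
`generateFlatScores()` adds Gaussian noise clipped to [0,1] (or uniform
"flip" noise) to the labels; at σ = 0.3 a 200-term × 500-gene instance
essentially always contains hierarchy violations, which is the problem
the engines exist to repair.

The generator makes no attempt to match real HPO topology statistics
(fan-out distributions, term-depth profiles, annotation sparsity
patterns) or realistic classifier error structure (noise here is
i.i.d. across terms, whereas real flat learners err in correlated
ways). Passing tests therefore demonstrate the algorithmic guarantees
and the mechanics of the pipeline, not genome-scale performance claims.

## Problem sizes used in the shipped studies

Property checks run on random instances of up to 500 terms and 200
genes (100 instances across all engine variants). The hold-out study —
also rerun by `scripts/acceptance.R` — uses a 300-term, 6-level
ontology with 400 genes, σ = 0.3, a 70/30 gene split, TPR-W weight
tuned over {0.1, 0.3, 0.5, 0.7, 0.9} by 5-fold internal CV, repeated
over independent seeds; these sizes exercise every code path while
keeping a full run in the tens of seconds on one CPU. The paired
flat-vs-corrected Fmax difference is reported with a confidence
interval but no effect size is asserted: how much correction helps
depends on the quality of the flat scores (with near-perfect or
hopelessly noisy input there is little to gain), and the synthetic
conditions are not calibrated to any real dataset.

## Known limitations

* Only `is_a` relationships are treated as edges by the OBO reader;
  `part_of` and other relationship types are ignored.
* The kernel neighborhood scorer is a generic symmetric-normalized
  adjacency power; it exists so the pipeline runs end to end and is not
  a re-implementation of any published network-ranking method.
* The adaptive-threshold fit is direct (no internal CV option), and
  children aggregations other than the average (e.g. max) are not
  implemented.
* Merged ontology terms whose alternate ids collide have their
  annotations unioned during remapping.

```{r example}
dag  <- generateDAG(60, nLevels = 5, edgeDensity = 0.1, seed = 3)
ann  <- generateAnnotations(dag, 40, 3, seed = 4)
flat <- generateFlatScores(ann, sigma = 0.3, seed = 5)
nrow(checkConsistency(dag, flat))
corr <- tprCorrect(dag, flat, tprConfig("TF"))
nrow(checkConsistency(dag, corr))
reportSummary(evaluateScores(corr, ann, dag = dag))
```
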