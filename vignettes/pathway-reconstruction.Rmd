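---
title: "Reconstructing metabolic pathways with knowledge-constrained Bayesian networks"
author: "bnpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing metabolic pathways with knowledge-constrained Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnpath)
```

## The problem

Homology mapping projects an organism's genes onto curated reference
pathway maps and inherits the maps' edges. It is precise but incomplete: it
cannot place genes into unmapped gaps, and it can never propose a relation
that the chosen reference map does not already contain. Purely *ab initio*
network inference from expression data can propose new relations, but over
the unconstrained space of all gene pairs it produces many false positives.

`bnpath` implements the combination of the two: learn a Bayesian network
from expression data, but restrain the search space with relation-level
knowledge pooled across *all* reference pathway maps. Two constraint sets
drive this:

* **required edges** — the gene-level expansion of the relations of the
  initially mapped (seed) pathway; these are present in every candidate
  graph and no local operation may remove or reverse them;
* **allowed edges** — every ordered gene pair whose KEGG Orthology (KO)
  groups are linked by *some* relation or reaction record anywhere in the
  knowledgebase. A local operation never creates an edge outside this
  whitelist; everything else is excluded outright.

Because relations are shared at the level of individual KO pairs rather
than whole maps, the search can still introduce relations absent from the
seed pathway's own reference map — that is what lets the method close
mapping gaps — while the whitelist keeps the false-positive rate of free
search in check.

## The model and its score

Expression of gene $v$ is modelled as linear-Gaussian given its parents in
the directed acyclic graph $G$:

$$ x_v \mid x_{\mathrm{pa}(v)} \sim
   \mathcal{N}\!\left(\beta_{v0} + \textstyle\sum_{u \in \mathrm{pa}(v)}
   \beta_{vu} x_u,\; \sigma_v^2\right). $$

Graphs are scored with the Bayesian Information Criterion

$$ \mathrm{Score}(G : D) = \ell(\hat\theta_G : D)
   - \frac{\log M}{2}\,\mathrm{Dim}(G), $$

where $\ell$ is the maximized log-likelihood (natural logarithm), $M$ the
number of expression conditions, and $\mathrm{Dim}(G)$ the number of
independent parameters — per node one coefficient per parent plus the
intercept and the variance, i.e. $|\mathrm{pa}(v)| + 2$. Parameters are
maximum-likelihood estimates: ordinary least squares coefficients and the
ML residual variance (residual sum of squares over $M$, not $M - p$),
floored at $10^{-6}$ so that exactly collinear or constant data cannot
produce an infinite density. The score decomposes over node families;
`bicScore()` reports the per-node contributions and the search updates
only the families a move touches.

Search is greedy hill climbing over the three local operations — add,
remove, reverse — starting from the seed graph. Each iteration enumerates
every legal operation, applies the one with the largest score gain, and
stops when no operation improves the score by more than $10^{-9}$ (the
tolerance guards against floating-point livelock). Ties between equal-best
moves break deterministically: add before remove before reverse, then
lexicographically by edge, so a run is a pure function of its inputs.
Reversal is treated strictly: the reversed orientation must itself be in
the whitelist, the stronger reading of "never generate an edge that is not
in the knowledgebase". `exhaustiveSearch()` enumerates every admissible
DAG on up to five genes and serves as the independent optimum in the test
suite.

### Known limitation: score plateaus

BIC cannot distinguish Markov-equivalent DAGs, so the landscape contains
plateaus of score-identical neighbours. A strict hill climber stops at the
first state where no single operation *strictly* improves the score, and
on data simulated from collider-rich truths it can end one plateau step
short of the optimum: at such stopping points the best legal move has a
delta of exactly zero. On four-gene problems simulated from random truth
DAGs this affects roughly one run in ten; on unstructured data the greedy
optimum and the exhaustive optimum coincide essentially always. The
package keeps the single strict greedy pass as the default (a restart
count is deliberately not bolted on, since the seeded search must stay a
deterministic function of its inputs) and treats score equality — not edge
orientation — as the asserted quantity wherever orientation is ambiguous.

## The knowledgebase

`parseKGML()` reads KGML pathway maps: `entry` elements become KO-bearing
enzyme nodes, compound nodes, or placeholders; each `relation` and
`reaction` element becomes one record with upstream and downstream KO
sets, a type, and any compounds. Entries may carry several KO numbers and
one KO may annotate several genes; both expand by cartesian product when
KO relations are transformed into gene relations — the maximal faithful
expansion. Self-edges are excluded everywhere (a Bayesian network has no
self-loops), but two distinct genes sharing a KO with an indexed self-pair
do yield cross-gene edges. Relation direction follows the KGML attribute
order (`entry1` upstream, `entry2` downstream). Records whose endpoints
cannot be resolved to a non-empty KO set — dangling entry ids, map-type
placeholders — are skipped with a counted warning rather than failing the
map, since real KGML files contain such entries. A KGML `reaction` element
names one catalysing entry plus substrate/product compounds; its record
carries the catalyst's KOs on both sides and contributes its compounds to
`attachCompounds()`, which decorates each predicted edge with the union of
compounds over all records supporting any KO pair of its endpoints.

Duplicate records across maps are retained (provenance) but collapse onto
one entry of the ordered-KO-pair index. An exclusion list
(`excludeMaps`) allows withholding the target organism's own maps when the
knowledgebase must not leak the answer; whether to exclude them from the
relation index as well as from mapping is left to configuration.

Metabolic maps are frequently cyclic, while the learned graph must be a
DAG. When the gene-level expansion of a seed pathway contains a directed
cycle, `initialMap()` repeatedly locates a cycle and drops its
lexicographically first edge until the seed is acyclic. A dropped edge is
not lost: the knowledgebase whitelist still contains it, so the search may
restore one orientation. Seed genes without expression measurements are
dropped from the graph with a log message — a node the model cannot score
cannot be carried.

## Preprocessing, clustering, and gene sampling

Genes with *more than* 20% missing conditions are removed
(`filterMissing()`; exactly 20% survives — the threshold is strict).
Remaining gaps are imputed, by default with the gene's own observed mean;
a k-nearest-neighbour alternative (k = 10, Euclidean distance over shared
observed conditions) is provided, and the choice is recorded in the run
metadata. No normalisation or batch correction is attempted.

Clustering uses a diagonal-covariance Gaussian mixture over gene profiles,
fitted by EM (seeded k-means initialisation, convergence at relative
log-likelihood change below $10^{-6}$ or 500 iterations, variances floored
at $10^{-6}$). The component count is chosen by 10-fold cross-validation
over genes on mean held-out log-likelihood, ties toward the smaller k; the
fold protocol is a package choice, as is diagonal covariance (the default
behaviour of the EM clustering tools this mirrors). All stochastic
routines take explicit seeds; there is no hidden RNG state.

For a seed pathway, the cluster containing most of its genes is the
*pivotal cluster* (ties to the lower index). Additional candidate genes
are drawn cluster-first: cluster $c$ is selected with probability
proportional to $1/(1 + d(c, \mathrm{pivot}))$, $d$ the Euclidean distance
between cluster means — the exact inverse-distance form is unspecified
territory; $1/(1+d)$ keeps the pivot's weight finite and maximal — then a
uniformly random unused gene is taken from it, without replacement,
renormalising over non-exhausted clusters. The number of genes to draw
defaults to the rounded (half-up, floor 1) mean enzyme-entry count of the
reference maps. Each stochastic run re-samples its gene set.

## Evaluation

Predictions are compared with target pathways on relational edges:
*recall* is the fraction of target edges recovered, *precision* the
fraction of predicted edges present in the target. Whether a match must
respect orientation is an open convention, so both modes exist;
`directed` is the default and the mode is recorded in the output. Since
required (seeded) edges are inherited rather than inferred, precision is
additionally reported with them excluded. Repeated stochastic runs are
summarized by minimum, lower quartile, median, upper quartile and maximum
(type-7 linear interpolation, stated in the output metadata), and
`compareMethods()` counts per-instance median wins between two methods,
ties separately.

## The synthetic benchmark generator

`generateBenchmarkBundle()` builds everything a full run needs from one
seed: a random truth DAG (random topological order, independent edge
inclusion), expression sampled ancestrally from its linear-Gaussian model,
a one-KO-per-gene map (a multi-KO mode exercises the cartesian expansion),
a reference KGML map exposing half of the truth (the seed pathway), and a
knowledgebase KGML map holding the corrupted whitelist — the truth minus a
dropped fraction plus a decoy fraction of random false ordered pairs.

Default benchmark conditions: 8–12 genes, 500–1,000 conditions, edge
coefficients of magnitude 0.8 with random sign, unit noise, 50% decoy
edges, no dropped edges. These make desk-scale recovery statistically
comfortable while leaving the decoys genuinely confusable. Coefficients
are parameterised as a magnitude interval plus a sign flag because a
single uniform interval cannot express both "fixed ±0.8 effects" and the
deterministic chain used in degenerate tests. The generator emulates the
statistical structure the learner assumes — linear effects, Gaussian
noise, a faithful whitelist superset — and deliberately does *not* mimic
real expression covariance, KEGG map topology statistics, measurement
batch structure, or non-linear regulation. Green tests on these bundles
certify the machinery (parsing, constraint assembly, scoring, search,
evaluation), not performance on real organisms.

The test suite and the acceptance script run at desk scale — 4-gene
instances against the exhaustive oracle (100 instances, $M = 500$),
8-gene bundles for the constrained-versus-unconstrained comparison (50
replicates, $M = 1000$), 90-gene three-component mixtures for
cluster-count recovery (20 draws) — sizes chosen so the full battery runs
in a couple of minutes while keeping the Monte-Carlo assertions
well-powered.

## Worked example

```{r example, eval = FALSE}
library(bnpath)

b <- generateBenchmarkBundle(nNodes = 8, M = 500, seed = 3)
ref <- parseKGML(b$kgmlDocs$reference)
kb  <- buildKnowledgebase(lapply(b$kgmlDocs, parseKGML))

seed_graph <- initialMap(ref, b$komap)
init <- PathwayGraph(nodes(b$truth), edges(seed_graph))
cons <- buildConstraints(init, kb, b$komap, nodes(b$truth))

fit <- greedySearch(init, b$data, cons)
fit$score
evaluateEdges(fit$graph, b$truth)
```

## Limitations

* Feedback loops cannot be represented: the model class is acyclic, while
  real metabolic maps contain cycles. Cyclic target edges are compared to
  DAG predictions through the direction-mode option.
* BIC identifies equivalence classes, not orientations; individual edge
  directions in the output should be read accordingly.
* The greedy search performs a single strict pass and can stop on a score
  plateau (see above).
* The knowledgebase is only as complete as the supplied KGML maps; an
  edge absent from every map can never be predicted.
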