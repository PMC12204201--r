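---
title: "Signalling entropy rates and their stabilisation: models and methods"
author: "entropin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signalling entropy rates and their stabilisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropin)
```

## The model

Signalling entropy quantifies the promiscuity of information flow in a
cell: a sample whose signalling mass spreads evenly over many interaction
partners has high entropy, one whose flow is channelled through few
partners has low entropy. entropin computes this from two inputs: an
undirected protein interaction network (PIN) and a nonnegative genes x
samples expression matrix.

For a sample $s$, the walk over the PIN follows the *mass-action
principle*: the intensity of the interaction between neighbouring genes
$i$ and $j$ is proportional to the product of their expression values,
$E_{is}E_{js}$. Row-normalising these intensities gives the transition
probabilities

$$p_{ij} = \frac{E_{is}E_{js}}{\sum_{k \in N_i} E_{is}E_{ks}}, \qquad j \in N_i,$$

where $N_i$ is the neighbour set of $i$. Note that $E_{is}$ cancels
within each row: the walk leaving $i$ only depends on the expression
*ratios* among $i$'s neighbours. Two consequences are worth knowing:
rescaling a whole sample by a positive constant changes nothing, and a
gene's own expression does not alter its outgoing distribution, only the
distributions of its neighbours.

Each node's *local entropy* is the Shannon entropy of its outgoing
distribution, $S_i = -\sum_{j \in N_i} p_{ij}\log p_{ij}$ (natural
logarithm throughout; $0\log 0 = 0$). Its normalised form divides by the
maximum attainable value, $\tilde S_i = S_i / \log k_i$ for degree
$k_i \ge 2$.

Two global rates summarise a sample:

* the **equilibrium entropy rate**
  $SR_{eq} = \sum_i \pi_i S_i / M_R$, the stationary-distribution-weighted
  mean of the raw local entropies, scaled by the network's maximum entropy
  rate $M_R$; and
* the **non-equilibrium entropy rate**
  $SR_{neq} = \frac1n\sum_i \tilde S_i$, the plain mean of the normalised
  local entropies, which lies in $[0,1]$ and needs no stationary
  distribution.

The mass-action chain is reversible (its edge weights $E_iE_j$ are
symmetric), so the stationary distribution has the closed form
$\pi_i \propto E_i \sum_{k \in N_i} E_k$. `stationary_distribution()`
uses this closed form and then *asserts* the fixed-point condition
$\|\pi P - \pi\|_\infty < 10^{-10}$; the test suite additionally checks it
against a dense power-iteration oracle (run on the lazy chain $(I+P)/2$,
which shares $\pi$ but converges on bipartite graphs too).

### Numerical and convention choices

* **$M_R$.** We take $M_R = \log\lambda_{\max}$, the log of the dominant
  adjacency eigenvalue — the maximum entropy rate achievable by any
  stationary walk on the graph. It depends only on topology. On a
  complete graph with uniform expression $SR_{eq} = 1$ exactly, which the
  tests verify for $K_3$ through $K_{20}$.
* **Degree-1 nodes.** $\tilde S_i = S_i/\log k_i$ is $0/0$ at $k_i = 1$;
  we define $\tilde S_i = 0$ there. A single-partner gene has no routing
  freedom, so zero normalised promiscuity is the natural reading.
* **Zeros in expression.** Zeros would leave transition rows undefined,
  so `integrate_system()` replaces them per sample with one tenth of that
  sample's smallest positive value (configurable via `epsilon`). The
  replacement is logged. No other preprocessing (log transform, quantile
  normalisation) is applied internally — scale invariance makes
  per-sample rescaling irrelevant, and anything else is the caller's
  decision.
* **Connectivity.** The equilibrium rate is computed on the largest
  connected component (the stationary distribution does not exist
  elsewhere); the non-equilibrium rate uses every integrated node. Ties
  between equally large components break toward the lexicographically
  smallest node-name set, so results do not depend on internal vertex
  ordering.

## Perturbation null models

Four operators distort a reference PIN by a fraction `level` of its
*original* edge count (count = `round(level * |E|)`, half-up), emulating
database errors:

* `add` inserts edges between uniformly sampled non-adjacent pairs
  (false positives);
* `remove` deletes uniformly sampled edges (false negatives);
* `flip` relocates existing edges to random non-adjacent pairs — edge
  count preserved, degrees not. "Flipping" has several readings in the
  literature (direction reversal only makes sense for directed graphs);
  relocation is the committed one, chosen because it is the edge-count
  preserving counterpart of addition and behaves accordingly;
* `rewire` performs degree-preserving double-edge swaps until the
  requested fraction of original edges has been displaced, erroring with
  the achieved fraction if `10 * |E|` proposals do not suffice (a
  triangle, for instance, admits no valid swap).

All operators are deterministic given a seed. Sweep cells derive their
seed from `(seed, kind, level, replicate)` with an FNV-style hash, so any
cell of a sweep can be reproduced in isolation, and perturbations at
different levels are independent draws rather than nested trajectories.

## Edge reliability scoring and filtering

Reliability scores live in a separate table (`reliability_scores`), not
on the graph; every method emits values in $[0,1]$.

**Topological** (`topological_scores()`): Jaccard on neighbour sets
excluding the two endpoints; Czekanowski–Dice on closed neighbourhoods
$N_x \cup \{x\}$ (so the interaction itself counts as shared context);
inverse log-weighted, $\sum_{z \in N_i \cap N_j} 1/\log k_z$, min–max
rescaled over the scored edges because thresholding needs a $[0,1]$
range (a common neighbour necessarily has $k_z \ge 2$, so the log is
positive; if all raw scores coincide the rescaling is degenerate and all
edges score 1, with a warning).

**Semantic** (`semantic_edge_scores()`): terms get information content
$IC(t) = -\log p(t)$ from true-path-propagated annotation frequencies;
term pairs are compared by Resnik (normalised by the corpus maximum IC),
Lin, Jiang–Conrath (similarity $1 - \min(1, d)$ on the IC distance in
nats), Schlicker's relevance measure, or Wang's graph-based measure with
the customary contribution factors 0.8 (`is_a`) and 0.6 (`part_of`).
Gene pairs combine term scores by the best-match average. Lin-type
ratios at $0/0$ (both terms with zero IC) score 0. The test suite checks
every IC-based measure against a brute-force common-ancestor enumeration
and Wang against an exhaustive path-product oracle on random DAGs.

**STRING** (`load_string_scores()`): combined confidence scores 0–1000
divided by 1000; duplicate pairs keep the maximum.

`filter_network()` keeps edges with score at least the threshold. Edges
*missing* from the score table count as score 0 and are removed at any
positive threshold: an interaction with no supporting evidence is exactly
the suspected false positive the protocol targets. This policy can shrink
networks aggressively when score coverage is partial, which is why the
filter reports `n_unscored` in its statistics.

## Group comparison and error tallies

Between-class differences in entropy rates use the two-sided Wilcoxon
rank-sum test (exact for combined $n \le 20$ without ties, normal
approximation with continuity correction otherwise; fully tied data
scores $p = 1$). A Welch t-test is selectable but non-default. The
within-class check repeatedly splits one class into disjoint random
halves and records the p-value distribution; the median over (default)
50 splits summarises it. `evaluation_grid()` crosses systems,
correction methods and thresholds, always including an uncorrected
baseline, and `count_errors()` tallies at $\alpha = 0.05$ the cells that
lose between-class significance and those that manufacture within-class
significance. Raw p-values are used throughout — the grid is a stability
diagnostic, not a discovery screen, so no multiplicity correction is
applied.

## The synthetic data generator

The generator exists so the whole pipeline is testable without network
downloads. It emulates four ingredients:

* **Interactome**: Barabási–Albert preferential attachment
  (`generate_network()`), built in-package so the edge count is exactly
  $m(n-m)$ and the graph is connected by construction; fitted degree
  exponents land near 3, within the 2–3 band typical of real
  interactomes at the low-degree end.
* **Expression**: per-gene log-normal baselines $b_g \sim
  \mathrm{LogNormal}(\mu, \sigma)$ shared across samples, with
  per-sample multiplicative noise $\exp N(0, \sigma_{noise})$. The
  dual-knockout class sets a freshly drawn pair of connected-component
  genes per sample to the integration epsilon (not literal zero, so the
  walk stays defined). Defaults: $\mu = 2$, $\sigma = 0.5$,
  $\sigma_{noise} = 0.1$. These are fixture values chosen once so that
  the wildtype / dual-KO contrast is reliably detectable at 20 samples
  per class on a 500-node interactome ($\sigma_{noise} = 0.2$ leaves the
  comparison underpowered — significant in only about 6 of 10 draws —
  which defeats the generator's purpose as a positive control).
* **Ontology**: a random single-rooted DAG with `is_a`/`part_of`
  relations and leaf-biased gene annotations, for exercising the
  semantic scorers.
* **Score tables**: Beta(8,2) scores for true edges versus Beta(2,8) for
  spurious ones — an informative but imperfect confidence score in the
  spirit of STRING's combined score.

### What the generator does and does not emulate

The expression model is noise around static baselines. It does **not**
simulate regulatory dynamics (the ODE machinery of simulators such as
GeneNetWeaver), so expression values carry no correlation structure
induced by the network itself. Consequences seen in the test suite:
perturbation trends (entropy rising under addition/flip/rewire, falling
under removal), knockout detectability, and score-based recovery of a
contaminated network all reproduce; but edge addition *dilutes* the
knockout contrast (the between-class gap shrinks, checked as a property)
rather than erasing its statistical significance outright, because the
sampling noise of the entropy rate shrinks alongside the effect as the
network densifies. Complete neutralisation of a knockout signature by
added edges appears to require expression–network coupling this
generator intentionally does not model. Passing tests therefore
demonstrate correctness of the machinery and the direction and relative
size of the effects, not quantitative agreement with any real dataset.

### Problem sizes

The shipped tests run the synthetic studies at 500 nodes ($m = 2$, 996
edges), 20 samples per class, 10 replicates per scenario, and 5
perturbation draws per sweep cell when level trends are assessed —
single draws leave hairline trend inversions (order $10^{-4}$) in about
a quarter of replicates from draw-to-draw variance alone, so level means
are averaged over draws before monotonicity is judged. Oracle
equivalence checks use 1000 random systems (stationary distribution),
100 random 50-term DAGs (semantic measures) and 50 random group pairs
(exact rank-sum enumeration).

## Power-law fitting

`fit_power_law()` implements the discrete maximum-likelihood estimator
with the likelihood normalised by the Hurwitz zeta function (evaluated
by Euler–Maclaurin summation) and, when `xmin` is not given, selects it
by Kolmogorov–Smirnov minimisation over candidate cutoffs. A continuous
closed-form approximation ($\hat\gamma = 1 + n/\sum\log(x_i/x_{min})$)
is available for analytic checks. On $10^5$ synthetic draws from a
$\gamma = 2.5$ law the discrete MLE agrees with igraph's independent
`plfit` implementation to about $10^{-5}$.

## Known limitations

* Directionality and edge weights in source networks are discarded; the
  entropy model is defined on symmetric neighbourhoods.
* $M_R$'s definition (log dominant eigenvalue) is a committed
  interpretation of "maximum reachable entropy rate"; alternative
  normalisations would rescale $SR_{eq}$ but not reorder samples.
* The missing-score-means-zero filtering policy conflates "no evidence"
  with "evidence against"; with sparse score coverage, prefer score
  tables that cover the network or use the uncorrected baseline for
  comparison.
* Semantic scoring treats the ontology file as given and does not choose
  among GO sub-ontologies or filter evidence codes.

## A minimal session

```{r example, eval = FALSE}
net <- generate_network(n_nodes = 500, m = 2, seed = 1)
gen <- generate_expression(net, n_samples = 20, seed = 1)
sys <- integrate_system(net, gen$expr)
tab <- entropy_table(sys)
head(tab)

wt <- gen$classes == "wildtype"
compare_groups(tab$sr_neq[wt], tab$sr_neq[!wt])

contaminated <- add_edges_random(net, level = 0.6, seed = 2)
tab2 <- entropy_table(integrate_system(contaminated, gen$expr),
                      measures = "neq")
compare_groups(tab2$sr_neq[wt], tab2$sr_neq[!wt])
```
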