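# entropin

Signalling entropy rates on protein interaction networks — and how to
keep them stable.

## The problem

Signalling entropy measures how promiscuously information flows through
a cell's signalling network. It is computed by integrating a sample's
expression profile with a protein interaction network (PIN): highly
entropic samples (stem cells, many cancers) spread their signalling mass
broadly, low-entropy samples channel it narrowly. The catch is that the
measure inherits every defect of the PIN. Interaction databases disagree
with each other and carry substantial false-positive rates, and both the
choice of database and random edge noise can flip the statistical
conclusions of an entropy comparison between biological conditions.

entropin is a toolkit for computing the global entropy rates, for
quantifying how network perturbations and database choice distort them,
and for stabilising comparisons by scoring edge reliability and
filtering unreliable interactions. It is aimed at computational
biologists comparing conditions (healthy vs tumour, stem vs
differentiated) through network entropy.

## The model

For sample *s*, neighbouring genes *i*, *j* interact with mass-action
intensity *E(i,s)·E(j,s)*; row-normalising gives the random-walk
transition matrix

> p(i,j) = E(i,s)·E(j,s) / Σ\_{k ∈ N(i)} E(i,s)·E(k,s)

Each node's local entropy S(i) = −Σ\_j p(i,j)·log p(i,j) (nats)
quantifies its signalling promiscuity. Two global rates summarise a
sample:

* **equilibrium rate** SR\_eq = Σ\_i π(i)·S(i) / M\_R, with π the
  stationary distribution of the walk (closed form π(i) ∝ E(i)·Σ\_{k ∈
  N(i)} E(k), the chain being reversible) and M\_R = log λ\_max the
  network's maximum entropy rate;
* **non-equilibrium rate** SR\_neq = mean of the normalised local
  entropies S(i)/log k(i), in [0, 1].

Around this core the package provides: edge-perturbation null models
(add / remove / flip / rewire at 10–90% of the interactome),
edge-reliability scoring (Jaccard, Czekanowski-Dice, inverse-log;
Resnik, Lin, Jiang-Conrath, Schlicker, Wang over an ontology; STRING
combined scores), threshold filtering, Wilcoxon-based between- and
within-class significance analysis with error tallies, and a synthetic
data module (scale-free interactomes, two-class expression with dual
knockouts, toy ontologies, ground-truth score tables) so everything is
testable offline. See the methods vignette
(`vignettes/entropin-methods.Rmd`) for the modelling choices.

## A worked example

```r
library(entropin)

net <- generate_network(n_nodes = 500, m = 2, seed = 1)   # scale-free PIN
gen <- generate_expression(net, n_samples = 20, seed = 1) # wildtype vs dual-KO
sys <- integrate_system(net, gen$expr)
tab <- entropy_table(sys)
head(tab, 3)
#>   sample sr_neq  sr_eq   m_r n_nodes n_edges_used
#> 1     s1 0.9370 0.7548 2.093     500          996
#> 2     s2 0.9356 0.7596 2.093     500          996
#> 3     s3 0.9353 0.7602 2.093     500          996

wt <- gen$classes == "wildtype"
compare_groups(tab$sr_neq[wt], tab$sr_neq[!wt])
#> wilcox test: p = 0.001116 (n = 20 vs 20, medians 0.9352 vs 0.9295)
```

Each row is one sample: `sr_neq` is the mean normalised local entropy
(the dual-knockout class sits consistently lower — two silenced genes
make their neighbours' signalling less promiscuous), `sr_eq` the
stationary-weighted rate scaled by the maximum entropy rate `m_r`
(2.093 nats here, so samples reach ~75% of the topology's ceiling). The
Wilcoxon p-value confirms the two classes separate on the clean
network. Contaminating the PIN with 60% random edges dilutes exactly
this contrast:

```r
contaminated <- add_edges_random(net, level = 0.6, seed = 2)
tab2 <- entropy_table(integrate_system(contaminated, gen$expr), measures = "neq")
compare_groups(tab2$sr_neq[wt], tab2$sr_neq[!wt])
#> wilcox test: p = 0.001116 (n = 20 vs 20, medians 0.9436 vs 0.9418)
```

— entropies inflate toward saturation (medians 0.9436 vs 0.9418, gap
roughly a third of the original) even though, at this noise level, the
rank separation itself survives. Reliability filtering
(`generate_score_table()` + `filter_network()` at threshold 0.4)
restores the clean-network picture; `evaluation_grid()` automates the
whole benchmark across correction methods and thresholds.

```r
fit_power_law(degree_histogram(net))
#> power-law fit (discrete MLE): gamma = 2.6904, xmin = 3, n_tail = 276, KS = 0.0282
```

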