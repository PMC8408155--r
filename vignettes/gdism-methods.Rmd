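---
title: "Machine-learned network dismantling and early-warning signals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learned network dismantling and early-warning signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdism)
```

# The problem

Network dismantling asks for a smallest set of nodes whose removal reduces
the largest connected component (LCC) of an undirected network below a
target size `t = ceiling(f * N)`, for a target fraction `f`. The problem is
NP-hard, so practical attacks rank nodes by a heuristic score and remove
them greedily. `gdism` implements a machine-learning approach: a graph
attention network (GAT) is trained to score each node with the probability
that it belongs to an *optimal* dismantling set, where the training signal
comes from exhaustive enumeration on small synthetic graphs — small enough
that the optimum is computable exactly.

The same scores support an early-warning statistic: by comparing the
cumulative score of nodes removed by an ongoing (possibly adversarial)
removal process against the score mass a model-guided attack would need to
collapse the network, one obtains a normalized indicator
$\Omega \in [0, 1]$ that rises towards 1 as the system approaches
collapse.

# Training data: exhaustive optima on small synthetic graphs

`generateNetwork()` draws small networks (default 25 nodes) from the three
classic random-graph families used for training — Barabási–Albert
preferential attachment, Erdős–Rényi, and static power-law — plus three
structured families used as benchmarks (`star`, `bridged_cliques`,
`clique_pair`). The synthetic families are a *proxy* for real networks:
they span heterogeneous (scale-free) and homogeneous (Poisson) degree
distributions, which is the structural axis that matters for attack
ranking, but they do not emulate any specific empirical system. The bet,
validated by the attack experiments, is that what makes a node critical is
a local property that transfers from small random graphs to large real
ones.

`bruteForceOptimalSets()` enumerates candidate removal sets in increasing
cardinality and returns *all* minimum sets achieving `LCC <= t`
(`t = ceiling(f * N)`; the ceiling makes the target attainable on every
graph and matches integer component sizes). Enumeration is exact and
therefore exponential; a `maxNodes` guard (default 30) refuses graphs
where it would be hopeless. The training label of node $n$ is

$$\ell(n) = \frac{|\{\text{optimal sets containing } n\}|}{|\{\text{optimal sets}\}|},$$

so labels lie in $[0, 1]$ and sum to the optimal set size $k$. A node in
every optimal set gets 1, a node in half of them 0.5:

```{r labels}
toy <- igraph::make_empty_graph(8, directed = FALSE)
igraph::V(toy)$name <- as.character(0:7)
toy <- igraph::add_edges(toy, c("0","1","0","2","0","3","0","4",
                                "4","5","5","6","6","7"))
sol <- bruteForceOptimalSets(toy, 0.25)
optimalSets(sol)
computeLabels(sol)
```

# Node features

Each node carries four structural features (`nodeFeatures()`): degree; the
$\chi^2$ statistic of its neighbours' degrees against their mean
($\sum_u (d_u - \bar d)^2 / \bar d$), which measures the heterogeneity of
the node's neighbourhood; the local clustering coefficient; and the
$k$-core number. All four are cheap, local, and size-free, which is what
allows a model trained on 25-node graphs to score million-node networks in
principle. Custom feature columns can be supplied as named numeric
vectors.

# The scoring model

`gdmConfig()` fixes the architecture inside the hyperparameter grid of the
method (convolution layers 1–4; channels {5, 10, 20, 30, 40, 50}; heads
{1, 5, 10, 15, 20, 30}; regressor widths {20, 30, 40, 50, 100}). The
default configuration — 3 attention layers of 30 channels with 10 heads,
followed by a 2-layer, 40-unit dense regressor — is the grid-search winner
reported by the method.

Each convolution layer combines a multi-head GAT block with a parallel
node-wise linear transform, *summing* the two outputs before an ELU
nonlinearity; attention logits use LeakyReLU with slope 0.2 over the
adjacency-plus-self-loop mask, and the heads are concatenated. The final
regressor ends in a sigmoid, so every node score is a probability. Fixed
training values: mean-squared-error loss against the enumeration labels,
Adam with learning rate $10^{-5}$, 50 epochs, one graph per optimization
step, and dropout 0.3. Three choices the method leaves open were resolved
as follows and are deliberate:

* **Dropout placement.** The method fixes $p = 0.3$ but not where dropout
  applies; it is applied to the attention coefficients after the softmax
  (the standard placement for GATs), during training only, with inverted
  scaling so evaluation needs no correction.
* **MSE + sigmoid.** Labels are fractions rather than classes, so
  regression with a sigmoid output is the natural reading of
  "probability of belonging to the optimal set".
* **Seeds.** `buildModel()` initializes weights (Glorot) from the config
  seed; `trainModel()` derives the shuffling/dropout stream from the same
  seed, so training is bit-reproducible.

The network is implemented twice: a plain-R reference (`R/nnet.R`) used by
the test suite as an oracle, and an exactly equivalent compiled
RcppArmadillo path that performs training. Both share R's RNG, and the
test suite checks they agree to machine precision, with gradients also
validated against central finite differences.

```{r train, eval = FALSE}
corpus <- buildTrainingCorpus(150, 25, seed = 41)
model <- trainModel(buildModel(gdmConfig(seed = 42)), corpus)
```

`gridSearchSelect()` reproduces the model-selection step: it trains one
model per candidate configuration and keeps the one with the lowest mean
dismantling AUC on held-out validation graphs (ties broken by fewer total
removals, then by configuration order).

# Attacks, AUC, reinsertion

`staticAttack()` ranks all nodes once by score (descending; ties broken by
ascending node id so runs are reproducible) and walks the ranking,
removing a node only if it currently belongs to the LCC — removing
anything else cannot reduce the LCC, so such nodes are skipped without
consuming a removal. The attack stops at `LCC <= t`. One numerical subtlety:
on highly symmetric graphs (e.g. two equal-size components that alternate
as "the" LCC) a single pass over the ranking can end with skipped nodes
still needed; in that case the walk re-runs over the still-present nodes
in the same order, which is guaranteed to make progress. This multi-pass
extension is required for the attack to always meet its own contract.

Robustness is summarized by the area under the LCC curve over the removal
sequence, integrated with composite Simpson's rule on the unit-spaced
removal index (an odd number of intervals falls back to the trapezoid rule
on the last panel). Lower AUC means a better attack.

`greedyReinsertion()` post-processes an attack: any removed node whose
return leaves `LCC <= t` is reinserted, choosing at each step the node that
lands in the smallest component (ties by ascending id), until no single
reinsertion is possible. The surviving set is therefore minimal-by-
inclusion, though not necessarily minimum. `heuristicAttack()` provides
the classic degree/betweenness baselines, optionally recomputed after
every removal, plus their `inverse_*` variants that remove peripheral
nodes first (used as a "worst case" control in the early-warning
experiments).

```{r attack}
g <- generateNetwork("erdos_renyi", 30, list(p = 0.15), seed = 7)
sc <- stats::setNames(igraph::degree(g), igraph::V(g)$name)
tr <- staticAttack(g, sc, targetFraction = 0.10)
c(removals = length(removals(tr)), auc = aucValue(tr))
```

# Early warning of collapse

`computeBaseline()` runs the model-guided static attack on the intact
network and accumulates the scores of the removed nodes up to the
*collapse point* — the first peak of the second-largest component (SLCC),
the standard percolation marker. That score mass is $\Omega_m$, the
"cost" of a model-efficient collapse. The default `slcc_peak` mode is
preferred to the alternative `target` mode (accumulate over the full
attack) because warnings should reference the moment the network breaks
apart, not the later moment the attack's bookkeeping target is reached.

For an arbitrary removal process with cumulative score mass $\Omega_s$,

$$\Omega = \min\!\left(\frac{\Omega_s}{\Omega_m},\, 1\right),$$

computed by `omegaValue()`. `omegaTrace()` evaluates $\Omega$ after each
removal of an attack, together with its increments and the LCC/SLCC
series, and `firstResponseTime()` reports how many removals before the
SLCC peak the trajectory first crossed the warning level (default 0.5).
An effective attack spends score mass quickly, so $\Omega$ crosses the
level well before collapse; an attack on peripheral nodes accumulates
almost nothing. `apTrace()` complements $\Omega$ with a purely structural
indicator: the number of articulation points over the course of the
removal sequence.

# Sizes, defaults and limitations

Defaults follow the method: training graphs of 25 nodes, label target
fraction 0.18, dismantling target fraction 0.10, warning level 0.5. The
package's own experiments (in the test suite) use corpora of 150–500
networks, which train in minutes on one CPU.

Limitations worth knowing:

* The forward pass materializes the $N \times N$ attention mask densely,
  so scoring is practical to a few thousand nodes; the method's
  large-scale regime would need a sparse attention implementation.
* Exhaustive enumeration limits training graphs to roughly 30 nodes; the
  approach relies on locality to generalize beyond that.
* $\Omega$ depends on the trained model: a model whose score mass
  concentrates poorly on a given topology yields baselines with little
  contrast (the test suite's two-clique experiment shows the intended
  behaviour with the generic synthetic training corpus).
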