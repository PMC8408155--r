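# gdism

Machine-learned network dismantling and early-warning signals of collapse.

Network dismantling asks for a smallest set of nodes whose removal breaks a
network's largest connected component (LCC) below a target size
`t = ceiling(f * N)`. The problem is NP-hard; `gdism` implements a
machine-learning attack: a multi-head graph attention network (GAT) is
trained on thousands of small synthetic graphs whose *optimal* dismantling
sets are computed exactly by exhaustive enumeration, learning to score each
node with the probability `p_n` that it belongs to an optimal set. Node
`n`'s training label is

    label(n) = |{optimal sets containing n}| / |{optimal sets}|

and each node carries four cheap local features (degree, neighbourhood
degree chi-square, local clustering, k-core number), so the learned scoring
transfers from 25-node training graphs to much larger networks. Scores
drive a static ranked attack with greedy reinsertion, and double as an
early-warning statistic

    Omega = min(Omega_s / Omega_m, 1)

that compares the cumulative score `Omega_s` removed by an ongoing process
against the score mass `Omega_m` a model-guided attack needs to reach the
collapse point (the peak of the second-largest component). `Omega` rises to
1 as the system approaches collapse; effective attacks cross the warning
level well before the collapse itself.

## Worked example

Build a labelled corpus (each graph solved exactly by enumeration), train
the default configuration (3 attention layers, 30 channels, 10 heads,
2-layer 40-unit regressor; MSE, Adam, lr 1e-5, 50 epochs, dropout 0.3):

```r
library(gdism)
corpus <- buildTrainingCorpus(150, nNodes = 25, seed = 1)
corpus[[1]]
#> TrainingSample: N = 25, E = 65, generator = erdos_renyi, k = 10

model <- trainModel(buildModel(gdmConfig(seed = 2)), corpus)
loss <- attr(model, "history")$loss
round(c(first = loss[1], last = loss[length(loss)]), 6)
#>    first     last
#> 0.136472 0.044347
```

Dismantle an unseen 200-node Barabási–Albert network to a 10% LCC target:

```r
g <- generateNetwork("barabasi_albert", 200, list(m = 2), seed = 99)
scores <- predictScores(model, g)
attack <- staticAttack(g, scores, targetFraction = 0.10)
attack
#> DismantlingTrace: 35 removal(s) on N = 200, LCC 200 -> 17 (target <= 20), AUC = 24.6800

pruned <- greedyReinsertion(g, attack)
c(before = length(removals(attack)), after = length(removals(pruned)))
#> before  after
#>     35     31

c(gdm = aucValue(attack), degree = aucValue(heuristicAttack(g, "degree", 0.10)))
#>      gdm   degree
#> 24.68000 23.90667
```

Thirty-one removals out of 200 nodes suffice after reinsertion. On a pure
preferential-attachment graph the degree heuristic is nearly optimal, and
the learned attack matches it within ~3% of AUC (the Simpson-rule area
under the LCC curve; lower is better) — the method's advantage on real
networks comes from structures degree cannot see.

Early warning on a two-clique system (two 25-cliques joined by 10
bridges): a recomputed-betweenness attack dismantles the bridges, and
`Omega` crosses the 0.5 warning level four removals before the collapse.

```r
toy <- generateNetwork("clique_pair", 50, list(cliqueSize = 25, nBridges = 10), seed = 77)
baseline <- computeBaseline(model, toy, targetFraction = 0.1)
baseline
#> OmegaBaseline: |S_o| = 10, omega_m = 2.9400

btw <- heuristicAttack(toy, "betweenness", 0.1, recompute = TRUE)
ew <- omegaTrace(model, toy, btw, baseline = baseline)
round(omegaSeries(ew), 3)
#>  [1] 0.1 0.2 0.3 0.4 0.5 0.6 0.7 0.8 0.9 1.0 1.0 1.0 ...
c(collapse = collapseIndex(ew), frt = firstResponseTime(ew))
#> collapse      frt
#>       10        4
```

An inverse-betweenness attack (peripheral nodes first) accumulates score
mass more slowly at every step, as an ineffective attack should:

```r
inv <- omegaTrace(model, toy,
                  heuristicAttack(toy, "inverse_betweenness", 0.1, recompute = TRUE),
                  baseline = baseline)
round(omegaSeries(inv)[1:10], 4)
#>  [1] 0.0723 0.1445 0.2168 0.2890 0.3613 0.4336 0.5058 0.5781 0.6503 0.7226
```

## Command line

A thin CLI over the same functions lives at `inst/cli/gdm.R`
(installed under `system.file("cli", "gdm.R", package = "gdism")`):

```sh
Rscript inst/cli/gdm.R generate-corpus --n-networks 200 --seed 1 --out corpus/
Rscript inst/cli/gdm.R train --corpus corpus/ --out model.ckpt
Rscript inst/cli/gdm.R dismantle --edges net.edges --model model.ckpt --target 0.10 --reinsert --out run1/
Rscript inst/cli/gdm.R early-warning --edges net.edges --model model.ckpt --strategy betweenness --recompute --out ew1/
Rscript inst/cli/gdm.R ap-trace --edges net.edges --attack "3,17,5" --out ap.csv
Rscript inst/cli/gdm.R baseline-attack --edges net.edges --strategy degree --out base1/
```

Every option can come from a flat `key=value` file via `--config`;
explicit flags win. Output directories contain the trace CSV plus a
manifest recording version, config and seed; identical inputs reproduce
identical files.

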