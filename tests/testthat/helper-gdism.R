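# Independent oracle: exhaustive enumeration of minimum dismantling sets in
# plain R (utils::combn + igraph component sizes), sharing no code with the
# compiled union-find enumerator it cross-checks.
rOptimalSets <- function(g, targetFraction) {
  n <- igraph::vcount(g)
  t <- ceiling(targetFraction * n)
  ids <- sort(as.integer(igraph::V(g)$name))
  lccAfter <- function(rm) {
    keep <- setdiff(ids, rm)
    if (length(keep) == 0L) return(0L)
    h <- igraph::induced_subgraph(g, as.character(keep))
    max(igraph::components(h)$csize)
  }
  if (lccAfter(integer(0)) <= t) return(list(k = 0L, sets = list(integer(0))))
  for (k in seq_len(n)) {
    cmb <- utils::combn(ids, k)
    hits <- list()
    for (j in seq_len(ncol(cmb))) {
      if (lccAfter(cmb[, j]) <= t) hits[[length(hits) + 1L]] <- cmb[, j]
    }
    if (length(hits)) return(list(k = k, sets = hits))
  }
}

setKeys <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))

# small named path graph 0-1-...-(n-1)
pathGraph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n) - 1L)
  g
}

ringGraph <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- as.character(seq_len(n) - 1L)
  g
}

# hub 0 with leaves 1,2,3 plus tail 0-4-5-6-7: exactly two minimum
# dismantling sets {0,5} and {0,6} at LCC target 2 (fraction 0.25)
twoSolutionToy <- function() {
  g <- igraph::make_empty_graph(8, directed = FALSE)
  igraph::V(g)$name <- as.character(0:7)
  igraph::add_edges(g, c("0", "1", "0", "2", "0", "3", "0", "4",
                         "4", "5", "5", "6", "6", "7"))
}

# shared trained models, built once per test run
.modelCache <- new.env(parent = emptyenv())

# study-condition model for the recovery experiment: 500 networks with a
# structurally forced optimal node (stars at label target 0.18, bridged
# cliques at 0.46 where the cut vertex is the unique optimum), default
# architecture, 50 epochs at the fixed training values
trainedRecoveryModel <- function() {
  if (is.null(.modelCache$recovery)) {
    stars <- buildTrainingCorpus(250, seq(15L, 25L, 2L), c(star = 1),
                                 targetFraction = 0.18, seed = 101)
    barb <- buildTrainingCorpus(250, seq(17L, 25L, 2L),
                                c(bridged_cliques = 1),
                                targetFraction = 0.46, seed = 202)
    .modelCache$recovery <- trainModel(buildModel(gdmConfig(seed = 303)),
                                       c(stars, barb))
  }
  .modelCache$recovery
}

# generic-corpus model (the training distribution of the method) used by the
# early-warning experiment
trainedGenericModel <- function() {
  if (is.null(.modelCache$generic)) {
    corpus <- buildTrainingCorpus(150, 25, seed = 41)
    .modelCache$generic <- trainModel(buildModel(gdmConfig(seed = 42)),
                                      corpus)
  }
  .modelCache$generic
}

# tiny fast config inside the hyperparameter grid, for unit tests
tinyConfig <- function(epochs = 5L, ...) {
  gdmConfig(nConvLayers = 1L, convChannels = 5L, attentionHeads = 1L,
            regressorLayers = 1L, regressorWidths = 20L, epochs = epochs,
            ...)
}
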