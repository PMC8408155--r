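#' Generate a synthetic network
#'
#' Small synthetic networks are the training substrate of the scoring model:
#' they are cheap to generate in bulk and small enough to dismantle optimally
#' by exhaustive enumeration. Three random-graph families are supported
#' (`barabasi_albert`, `erdos_renyi`, `static_power_law`) plus two
#' deterministic families with a structurally forced critical node that are
#' useful as sanity and recovery benchmarks: `star` (one hub) and
#' `bridged_cliques` (two cliques joined through a single cut vertex).
#' `clique_pair` builds two cliques connected by `nBridges` disjoint border
#' edges, the classic illustration of a system whose LCC hides an imminent
#' split.
#'
#' @param model one of `"barabasi_albert"`, `"erdos_renyi"`,
#'   `"static_power_law"`, `"star"`, `"bridged_cliques"`, `"clique_pair"`.
#' @param n number of nodes (>= 2).
#' @param params named list of generator parameters: `m` (edges per new node,
#'   Barabasi-Albert, default 2), `p` (edge probability, Erdos-Renyi),
#'   `exponent` (> 2) and `m` (total edge count, default `2 * n`) for the
#'   static power-law model, `cliqueSize` for the clique families and
#'   `nBridges` for `clique_pair`.
#' @param seed integer seed; the same seed and parameters give an identical
#'   graph.
#' @return An igraph object with integer node ids `0..n-1` stored as vertex
#'   names, simple and undirected. Erdos-Renyi graphs may be disconnected.
#' @examples
#' g <- generateNetwork("erdos_renyi", 25, list(p = 0.2), seed = 7)
#' igraph::vcount(g)
#' @export
generateNetwork <- function(model, n, params = list(), seed) {
  if (missing(seed)) stop("a seed is required")
  if (!is.numeric(n) || n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  g <- switch(model,
    barabasi_albert = {
      m <- params$m %||% 2L
      if (m < 1 || m >= n) stop("barabasi_albert needs 1 <= m < n")
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    erdos_renyi = {
      p <- params$p
      if (is.null(p) || p < 0 || p > 1) {
        stop("erdos_renyi needs an edge probability p in [0, 1]")
      }
      igraph::sample_gnp(n, p)
    },
    static_power_law = {
      expo <- params$exponent %||% 2.5
      if (expo <= 2) stop("static_power_law needs exponent > 2")
      m <- params$m %||% (2L * n)
      igraph::sample_fitness_pl(n, no.of.edges = m, exponent.out = expo)
    },
    star = igraph::make_star(n, mode = "undirected", center = 1),
    bridged_cliques = {
      cs <- params$cliqueSize %||% ((n - 1L) %/% 2L)
      if (2L * cs + 1L != n) stop("bridged_cliques needs n = 2 * cliqueSize + 1")
      a <- igraph::make_full_graph(cs)
      b <- igraph::make_full_graph(cs)
      g2 <- igraph::disjoint_union(a, b)
      g2 <- igraph::add_vertices(g2, 1)
      # bridge node (last vertex) attaches to one node of each clique
      igraph::add_edges(g2, c(2L * cs + 1L, 1L, 2L * cs + 1L, cs + 1L))
    },
    clique_pair = {
      cs <- params$cliqueSize %||% (n %/% 2L)
      nb <- params$nBridges %||% 1L
      if (2L * cs != n) stop("clique_pair needs n = 2 * cliqueSize")
      if (nb < 1 || nb > cs) stop("nBridges must be in 1..cliqueSize")
      g2 <- igraph::disjoint_union(igraph::make_full_graph(cs),
                                   igraph::make_full_graph(cs))
      igraph::add_edges(g2, rbind(seq_len(nb), cs + seq_len(nb)))
    },
    stop("unknown generator model: ", model)
  )
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  g$generator <- model
  g$genParams <- params
  g$genSeed <- as.integer(seed)
  g
}

#' Enumerate all minimum dismantling sets of a small graph
#'
#' Exhaustively searches node subsets by increasing cardinality until, at
#' some size k, at least one subset reduces the largest connected component
#' to at most `t = ceiling(targetFraction * N)` nodes; all size-k subsets
#' achieving the target are returned. If the graph already satisfies the
#' target, k = 0 with a single empty set is returned. The search is
#' combinatorial, hence the hard cap on the node count.
#'
#' @param g igraph object.
#' @param targetFraction LCC target as a fraction of the node count,
#'   in (0, 1); default 0.18.
#' @param maxNodes safety cap on the node count (default 30).
#' @return An [OptimalSolutionSet-class]; sets are sorted node-id vectors in
#'   lexicographic order.
#' @examples
#' g <- igraph::make_ring(6)
#' sol <- bruteForceOptimalSets(g, targetFraction = 0.5)
#' optimalSize(sol)  # 2: nine node pairs split a 6-cycle into halves
#' @export
bruteForceOptimalSets <- function(g, targetFraction = 0.18, maxNodes = 30L) {
  g <- .ensureIds(g)
  n <- igraph::vcount(g)
  if (n > maxNodes) {
    stop("graph has ", n, " nodes, above the safety cap of ", maxNodes)
  }
  t <- .stopTarget(targetFraction, n)
  ids <- sort(.nodeIds(g))
  res <- cpp_optimal_sets(n, .edgeMatrix0(g, ids), t, n)
  sets <- lapply(res$sets, function(ix) as.integer(ids[ix]))
  new("OptimalSolutionSet", targetSize = t, k = as.integer(res$k),
      sets = sets, nodes = ids,
      graphId = paste0("N", n, "E", igraph::ecount(g)))
}

#' Training labels from an optimal solution set
#'
#' The label of a node is the number of minimum dismantling sets it belongs
#' to divided by the total number of such sets; with a single optimal set the
#' labels are 1 for its members and 0 elsewhere, with two sets they are 1,
#' 0.5 or 0. Labels always sum to k over the whole graph.
#'
#' @param solutions an [OptimalSolutionSet-class].
#' @return Named numeric vector over all node ids, values in \[0, 1\].
#' @export
computeLabels <- function(solutions) {
  stopifnot(is(solutions, "OptimalSolutionSet"))
  if (length(solutions@sets) == 0L) stop("empty solution list")
  counts <- table(factor(unlist(solutions@sets), levels = solutions@nodes))
  lab <- as.numeric(counts) / length(solutions@sets)
  names(lab) <- as.character(solutions@nodes)
  lab
}

# parameter draw for one corpus sample; ranges follow common usage for
# sparse 25-node training graphs and are fully configurable
.drawParams <- function(model, n, ranges) {
  switch(model,
    barabasi_albert = list(m = sample(ranges$baM, 1L)),
    erdos_renyi = list(p = runif(1, ranges$erP[1], ranges$erP[2])),
    static_power_law = list(
      exponent = runif(1, ranges$plExponent[1], ranges$plExponent[2]),
      m = sample(seq.int(n, 2L * n), 1L)),
    list()
  )
}

#' Build a labeled training corpus
#'
#' Generates `nNetworks` synthetic graphs, dismantles each optimally by
#' exhaustive enumeration, converts set memberships to labels and computes
#' node features. The whole corpus is deterministic under `seed`.
#'
#' @param nNetworks number of networks (>= 1).
#' @param nNodes nodes per network (default 25); a vector is sampled
#'   uniformly per network.
#' @param generatorMix named numeric weights over generator models; names
#'   must be valid [generateNetwork()] models. Default: equal weights over
#'   the three random-graph families.
#' @param targetFraction LCC target for the optimal dismantling
#'   (default 0.18).
#' @param seed integer seed.
#' @param paramRanges list of draw ranges: `baM` (Barabasi-Albert m values,
#'   default 1:3), `erP` (Erdos-Renyi probability interval, default
#'   c(0.08, 0.25)), `plExponent` (power-law exponent interval, default
#'   c(2, 3)).
#' @param featureNames feature columns to precompute (see [nodeFeatures()]).
#' @return List of [TrainingSample-class] objects.
#' @export
buildTrainingCorpus <- function(nNetworks, nNodes = 25L,
                                generatorMix = c(barabasi_albert = 1,
                                                 erdos_renyi = 1,
                                                 static_power_law = 1) / 3,
                                targetFraction = 0.18, seed,
                                paramRanges = list(),
                                featureNames = c("degree", "chi2",
                                                 "clustering", "kcore")) {
  if (missing(seed)) stop("a seed is required")
  if (!is.numeric(nNetworks) || nNetworks < 1) stop("nNetworks must be >= 1")
  ranges <- utils::modifyList(
    list(baM = 1:3, erP = c(0.08, 0.25), plExponent = c(2, 3)), paramRanges)
  set.seed(as.integer(seed))
  models <- sample(names(generatorMix), nNetworks, replace = TRUE,
                   prob = generatorMix)
  seeds <- sample.int(.Machine$integer.max, nNetworks)
  nNodes <- as.integer(nNodes)
  sizes <- nNodes[sample.int(length(nNodes), nNetworks, replace = TRUE)]
  params <- lapply(seq_len(nNetworks),
                   function(i) .drawParams(models[i], sizes[i], ranges))
  lapply(seq_len(nNetworks), function(i) {
    g <- generateNetwork(models[i], sizes[i], params[[i]], seed = seeds[i])
    sol <- bruteForceOptimalSets(g, targetFraction)
    labels <- computeLabels(sol)
    feats <- nodeFeatures(g, featureNames)
    new("TrainingSample", graph = g, labels = labels, features = feats,
        provenance = list(generator = models[i], params = params[[i]],
                          seed = seeds[i], k = sol@k, t = sol@targetSize,
                          targetFraction = targetFraction))
  })
}

#' Serialize and restore a training corpus
#'
#' Each sample i is written as `<i>.edges` ("u v" per line), `<i>.labels`
#' ("node label" per line) and `<i>.info` (flat key=value manifest with the
#' generator, its parameters, the seed, k and the LCC target); a corpus-level
#' `manifest.txt` records the sample count and feature columns. Features are
#' recomputed on read.
#'
#' @param corpus list of [TrainingSample-class] objects.
#' @param dir corpus directory.
#' @param overwrite allow writing into an existing directory.
#' @return `writeCorpus` invisibly returns `dir`; `readCorpus` returns the
#'   corpus list.
#' @export
writeCorpus <- function(corpus, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop("directory exists; use overwrite = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  featureNames <- colnames(corpus[[1]]@features)
  for (i in seq_along(corpus)) {
    s <- corpus[[i]]
    el <- igraph::as_edgelist(s@graph, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), file.path(dir, paste0(i, ".edges")))
    ids <- sort(.nodeIds(s@graph))
    writeLines(paste(ids, format(s@labels[as.character(ids)], digits = 17)),
               file.path(dir, paste0(i, ".labels")))
    p <- s@provenance
    .writeKeyValues(list(
      generator = p$generator,
      params = paste(names(p$params), unlist(p$params), sep = ":",
                     collapse = ";"),
      seed = p$seed, k = p$k, t = p$t, n = igraph::vcount(s@graph)),
      file.path(dir, paste0(i, ".info")))
  }
  .writeKeyValues(list(nSamples = length(corpus),
                       featureNames = paste(featureNames, collapse = ",")),
                  file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(dir) {
  man <- .readKeyValues(file.path(dir, "manifest.txt"))
  nS <- as.integer(man$nSamples)
  featureNames <- strsplit(man$featureNames, ",")[[1]]
  lapply(seq_len(nS), function(i) {
    g <- readEdgeList(file.path(dir, paste0(i, ".edges")))
    lab <- utils::read.table(file.path(dir, paste0(i, ".labels")),
                             col.names = c("node", "label"))
    labels <- lab$label
    names(labels) <- as.character(lab$node)
    # isolated nodes are absent from the edge list but present in the labels
    missing <- setdiff(as.character(lab$node), igraph::V(g)$name)
    if (length(missing)) {
      g <- igraph::add_vertices(g, length(missing), name = missing)
    }
    info <- .readKeyValues(file.path(dir, paste0(i, ".info")))
    kvPairs <- strsplit(strsplit(info$params, ";")[[1]], ":")
    params <- lapply(kvPairs, function(x) as.numeric(x[2]))
    names(params) <- vapply(kvPairs, `[`, character(1), 1)
    new("TrainingSample", graph = g, labels = labels,
        features = nodeFeatures(g, featureNames),
        provenance = list(generator = info$generator, params = params,
                          seed = as.integer(info$seed), k = as.integer(info$k),
                          t = as.integer(info$t)))
  })
}
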