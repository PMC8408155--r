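test_that("generators honour node counts, simplicity and determinism", {
  g1 <- generateNetwork("erdos_renyi", 25, list(p = 0.2), seed = 7)
  expect_equal(igraph::vcount(g1), 25)
  g2 <- generateNetwork("erdos_renyi", 25, list(p = 0.2), seed = 7)
  expect_true(igraph::identical_graphs(g1, g2))

  ba <- generateNetwork("barabasi_albert", 25, list(m = 2), seed = 1)
  expect_equal(igraph::vcount(ba), 25)
  expect_true(igraph::is_connected(ba))

  pl <- generateNetwork("static_power_law", 25, list(exponent = 2.5), seed = 3)
  expect_true(igraph::is_simple(pl))
  expect_lte(max(igraph::degree(pl)), 24)

  expect_error(generateNetwork("watts_strogatz", 10, seed = 1), "unknown")
  expect_error(generateNetwork("erdos_renyi", 10, list(p = 1.5), seed = 1),
               "probability")
  expect_error(generateNetwork("erdos_renyi", 10, list(p = 0.2)), "seed")
})

test_that("brute force finds the known optima of structured graphs", {
  # middle node splits a 5-path into halves of size <= 2
  sol <- bruteForceOptimalSets(pathGraph(5), 0.4)
  expect_equal(optimalSize(sol), 1L)
  expect_equal(optimalSets(sol), list(2L))

  # removing the hub isolates all leaves
  star <- generateNetwork("star", 5, seed = 1)
  sol <- bruteForceOptimalSets(star, 0.2)  # t = 1
  expect_equal(optimalSize(sol), 1L)
  expect_equal(optimalSets(sol), list(0L))

  # 6-cycle at t = 3: all vertex pairs at cycle distance 2 or 3
  sol <- bruteForceOptimalSets(ringGraph(6), 0.5)
  expect_equal(optimalSize(sol), 2L)
  expect_equal(length(optimalSets(sol)), 9L)
  oracle <- rOptimalSets(ringGraph(6), 0.5)
  expect_equal(setKeys(optimalSets(sol)), setKeys(oracle$sets))

  # a graph already below the target needs no removal
  tiny <- pathGraph(2)
  sol <- bruteForceOptimalSets(tiny, 0.9)  # t = 2
  expect_equal(optimalSize(sol), 0L)
  expect_equal(optimalSets(sol), list(integer(0)))

  expect_error(bruteForceOptimalSets(ringGraph(31)), "safety cap")
  expect_error(bruteForceOptimalSets(ringGraph(5), 1.2), "targetFraction")
})

test_that("brute force agrees with the independent combn oracle", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(5:10, 1)
    g <- generateNetwork("erdos_renyi", n, list(p = runif(1, 0.2, 0.5)),
                         seed = 1000 + rep)
    tf <- runif(1, 0.2, 0.5)
    sol <- bruteForceOptimalSets(g, tf)
    oracle <- rOptimalSets(g, tf)
    expect_equal(optimalSize(sol), as.integer(oracle$k))
    expect_equal(setKeys(optimalSets(sol)), setKeys(oracle$sets))
  }
})

test_that("enumeration commutes with node relabeling", {
  g <- generateNetwork("erdos_renyi", 9, list(p = 0.35), seed = 5)
  sol <- bruteForceOptimalSets(g, 0.3)
  perm <- c(5L, 3L, 8L, 1L, 0L, 7L, 2L, 6L, 4L)  # old id i -> perm[i+1]
  gp <- g
  igraph::V(gp)$name <- as.character(perm[as.integer(igraph::V(g)$name) + 1L])
  solp <- bruteForceOptimalSets(gp, 0.3)
  mapped <- lapply(optimalSets(sol), function(s) sort(perm[s + 1L]))
  expect_equal(setKeys(mapped), setKeys(optimalSets(solp)))
})

test_that("labels encode optimal-set membership fractions", {
  # unique optimal set: members 1, all others 0
  lab <- computeLabels(bruteForceOptimalSets(pathGraph(5), 0.4))
  expect_equal(unname(lab[c("2")]), 1)
  expect_equal(sum(lab), 1)
  expect_true(all(lab[c("0", "1", "3", "4")] == 0))

  # exactly two optimal sets: shared node 1, exclusive nodes 0.5, rest 0
  toy <- twoSolutionToy()
  sol <- bruteForceOptimalSets(toy, 0.25)
  expect_equal(length(optimalSets(sol)), 2L)
  lab <- computeLabels(sol)
  expect_identical(unname(lab["0"]), 1)
  expect_identical(unname(lab["5"]), 0.5)
  expect_identical(unname(lab["6"]), 0.5)
  expect_true(all(lab[c("1", "2", "3", "4", "7")] == 0))

  # 6-cycle: every node in 3 of the 9 sets, sum equals k
  lab <- computeLabels(bruteForceOptimalSets(ringGraph(6), 0.5))
  expect_equal(unname(lab), rep(1 / 3, 6))
  expect_equal(sum(lab), 2)
})

test_that("training corpora are deterministic and label sums equal k", {
  c1 <- buildTrainingCorpus(8, 12, seed = 99, targetFraction = 0.25)
  c2 <- buildTrainingCorpus(8, 12, seed = 99, targetFraction = 0.25)
  expect_equal(length(c1), 8L)
  for (i in seq_along(c1)) {
    expect_equal(sum(c1[[i]]@labels), c1[[i]]@provenance$k)
    expect_equal(c1[[i]]@labels, c2[[i]]@labels)
    expect_true(igraph::identical_graphs(c1[[i]]@graph, c2[[i]]@graph))
    expect_true(all(c("generator", "params", "seed", "k", "t") %in%
                      names(c1[[i]]@provenance)))
  }
  expect_error(buildTrainingCorpus(0, seed = 1), "nNetworks")
  expect_error(buildTrainingCorpus(3, 12), "seed")
})

test_that("every optimal set of a corpus sample meets its LCC target", {
  corpus <- buildTrainingCorpus(5, 11, seed = 13, targetFraction = 0.3)
  for (s in corpus) {
    sol <- bruteForceOptimalSets(s@graph, s@provenance$targetFraction)
    ids <- sort(as.integer(igraph::V(s@graph)$name))
    for (set in optimalSets(sol)) {
      keep <- setdiff(ids, set)
      h <- igraph::induced_subgraph(s@graph, as.character(keep))
      expect_lte(max(igraph::components(h)$csize), sol@targetSize)
    }
  }
})

test_that("corpus serialization round-trips graphs, labels and provenance", {
  corpus <- buildTrainingCorpus(4, 10, seed = 3, targetFraction = 0.3)
  dir <- file.path(tempdir(), "corpus-rt")
  unlink(dir, recursive = TRUE)
  writeCorpus(corpus, dir)
  expect_error(writeCorpus(corpus, dir), "overwrite")
  back <- readCorpus(dir)
  expect_equal(length(back), 4L)
  for (i in seq_along(corpus)) {
    a <- corpus[[i]]; b <- back[[i]]
    expect_equal(sort(igraph::V(a@graph)$name), sort(igraph::V(b@graph)$name))
    ela <- apply(igraph::as_edgelist(a@graph), 1, function(e)
      paste(sort(as.integer(e)), collapse = "-"))
    elb <- apply(igraph::as_edgelist(b@graph), 1, function(e)
      paste(sort(as.integer(e)), collapse = "-"))
    expect_equal(sort(ela), sort(elb))
    expect_equal(a@labels[names(b@labels)], b@labels)
    expect_equal(a@provenance$k, b@provenance$k)
    expect_equal(a@provenance$generator, b@provenance$generator)
  }
  unlink(dir, recursive = TRUE)
})
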