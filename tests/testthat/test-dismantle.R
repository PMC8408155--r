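test_that("static attack follows scores, skip rule and stop condition", {
  # star with 10 leaves, hub scored highest, target 0.10 (t = 2)
  star <- generateNetwork("star", 11, seed = 1)
  sc <- stats::setNames(c(1, rep(0.1, 10)), as.character(0:10))
  tr <- staticAttack(star, sc, 0.10)
  expect_equal(removals(tr), 0L)
  expect_equal(lccSizes(tr), c(11L, 1L))

  # graph already below the target: no removals
  g <- pathGraph(3)
  sc <- stats::setNames(rep(0.5, 3), as.character(0:2))
  tr <- staticAttack(g, sc, 0.9)
  expect_length(removals(tr), 0)

  # a top-scored node outside the current LCC is skipped, not removed:
  # triangle 0-1-2 (scored highest) next to a K4 3-6
  f <- withr::local_tempfile()
  writeLines(c("0 1", "1 2", "2 0", "3 4", "3 5", "3 6", "4 5", "4 6",
               "5 6"), f)
  g <- readEdgeList(f)
  sc <- stats::setNames(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.1),
                        as.character(0:6))
  tr <- staticAttack(g, sc, 0.15)  # t = 2
  expect_false(removals(tr)[1] %in% 0:2)  # K4 is the LCC at step 1

  # missing score errors
  expect_error(staticAttack(g, sc[-1], 0.15), "cover every node")

  # idempotence: identical scores give identical traces
  tr2 <- staticAttack(g, sc, 0.15)
  expect_identical(removals(tr), removals(tr2))
  expect_identical(aucValue(tr), aucValue(tr2))
})

test_that("trace invariants hold on random attacks", {
  set.seed(10)
  for (rep in 1:5) {
    g <- generateNetwork("erdos_renyi", 20, list(p = 0.2), seed = 400 + rep)
    sc <- stats::setNames(runif(20), as.character(0:19))
    tr <- staticAttack(g, sc, 0.1)
    expect_true(all(diff(lccSizes(tr)) <= 0))
    expect_lte(lccSizes(tr)[length(lccSizes(tr))], ceiling(0.1 * 20))
    # every removed node was in the LCC at its removal time
    h <- g
    for (v in removals(tr)) {
      expect_true(v %in% gdism:::.lccMembers(h))
      h <- gdism:::.deleteIds(h, v)
    }
  }
})

test_that("Simpson AUC matches closed forms and respects dominance", {
  expect_equal(dismantlingAUC(c(1, 1, 1)), 2)
  expect_equal(dismantlingAUC(c(1, 0.5, 0.25)), (1 + 4 * 0.5 + 0.25) / 3,
               tolerance = 1e-12)
  expect_equal(dismantlingAUC(0.7), 0)
  expect_equal(dismantlingAUC(c(1, 0.5)), 0.75)  # single trapezoid panel
  # odd interval count: Simpson on the first two panels + trapezoid
  expect_equal(dismantlingAUC(c(1, 0.75, 0.5, 0.25)),
               (1 + 4 * 0.75 + 0.5) / 3 + (0.5 + 0.25) / 2, tolerance = 1e-12)
  expect_error(dismantlingAUC(numeric(0)), "empty")
  expect_error(dismantlingAUC(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (rep in 1:10) {
    a <- sort(runif(7), decreasing = TRUE)
    b <- pmax(a - runif(7, 0, 0.2), 0)  # pointwise dominated
    expect_lte(dismantlingAUC(b), dismantlingAUC(a))
  }
})

test_that("greedy reinsertion prunes unnecessary removals", {
  # path 0-1-2-3-4 with R = [2,3], target LCC <= 2: node 3 comes back
  g <- pathGraph(5)
  tr <- gdism:::.replayRemovals(g, c(2L, 3L), 0.4)
  out <- greedyReinsertion(g, tr)
  expect_equal(removals(out), 2L)
  expect_lte(max(lccSizes(out)[length(lccSizes(out))]), 2)

  # an isolated removed node is always reinserted
  g2 <- igraph::add_vertices(pathGraph(5), 1, name = "5")
  tr2 <- gdism:::.replayRemovals(g2, c(2L, 5L), 0.4)  # t = 3
  out2 <- greedyReinsertion(g2, tr2)
  expect_false(5L %in% removals(out2))

  # empty removal list is a fixed point
  tr3 <- gdism:::.replayRemovals(pathGraph(3), integer(0), 0.9)
  out3 <- greedyReinsertion(pathGraph(3), tr3)
  expect_length(removals(out3), 0)

  expect_error(greedyReinsertion(pathGraph(4), tr), "does not match")
})

test_that("reinsertion keeps the target and returns a maximal pruning", {
  set.seed(20)
  for (rep in 1:5) {
    g <- generateNetwork("erdos_renyi", 16, list(p = 0.25), seed = 500 + rep)
    sc <- stats::setNames(runif(16), as.character(0:15))
    tr <- staticAttack(g, sc, 0.2)
    out <- greedyReinsertion(g, tr)
    t <- ceiling(0.2 * 16)
    expect_lte(lccSizes(out)[length(lccSizes(out))], t)
    expect_lte(length(removals(out)), length(removals(tr)))
    expect_true(all(removals(out) %in% removals(tr)))
    # maximality: reinserting any remaining removed node breaks the target
    ids <- gdism:::.nodeIds(g)
    for (r in removals(out)) {
      keep <- setdiff(ids, setdiff(removals(out), r))
      h <- igraph::induced_subgraph(g, as.character(keep))
      expect_gt(max(igraph::components(h)$csize), t)
    }
  }
})

test_that("no attack beats the brute-force optimum on small graphs", {
  set.seed(30)
  for (rep in 1:8) {
    g <- generateNetwork("erdos_renyi", 11, list(p = 0.3), seed = 600 + rep)
    tf <- 0.25
    k <- optimalSize(bruteForceOptimalSets(g, tf))
    sc <- stats::setNames(runif(11), as.character(0:10))
    out <- greedyReinsertion(g, staticAttack(g, sc, tf))
    expect_gte(length(removals(out)), k)
  }
})

test_that("heuristic attacks rank by the named centrality", {
  star <- generateNetwork("star", 11, seed = 1)
  tr <- heuristicAttack(star, "degree", 0.10)
  expect_equal(removals(tr)[1], 0L)  # hub first

  trInv <- heuristicAttack(star, "inverse_degree", 0.5)  # t = 6
  expect_false(0L %in% removals(trInv))  # only leaves fall

  # two 5-cliques joined through one bridge node: betweenness removes it first
  bc <- generateNetwork("bridged_cliques", 11, list(cliqueSize = 5), seed = 1)
  trB <- heuristicAttack(bc, "betweenness", 0.4)
  expect_equal(removals(trB)[1], 10L)

  expect_error(heuristicAttack(star, "pagerank"), "arg")

  # recomputed attack reaches the target too
  trR <- heuristicAttack(bc, "betweenness", 0.2, recompute = TRUE)
  expect_lte(lccSizes(trR)[length(lccSizes(trR))], ceiling(0.2 * 11))
})
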