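test_that("configurations outside the hyperparameter grid are rejected", {
  expect_error(gdmConfig(nConvLayers = 5), "nConvLayers")
  expect_error(gdmConfig(convChannels = 17), "convChannels")
  expect_error(gdmConfig(attentionHeads = 3), "attentionHeads")
  expect_error(gdmConfig(regressorWidths = 64), "regressorWidths")
  expect_error(gdmConfig(dropout = 1), "dropout")
  expect_s4_class(gdmConfig(), "GDMConfig")
})

test_that("scores are sigmoid-bounded, symmetric and defined for all inputs", {
  model <- buildModel(tinyConfig(seed = 11))
  g <- generateNetwork("erdos_renyi", 15, list(p = 0.25), seed = 2)
  s <- predictScores(model, g)
  expect_length(s, 15)
  expect_true(all(s > 0 & s < 1))

  # vertex-transitive graph: identical scores everywhere
  ring <- ringGraph(8)
  sr <- predictScores(model, ring)
  expect_equal(max(sr) - min(sr), 0)

  # a single-node graph still gets one score (self-only aggregation)
  solo <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(solo)$name <- "0"
  expect_length(predictScores(model, solo), 1)

  # graph with an isolated node: all scores finite and in range
  g2 <- igraph::add_vertices(pathGraph(4), 1, name = "9")
  s2 <- predictScores(model, g2)
  expect_true(all(is.finite(s2)) && length(s2) == 5)
})

test_that("the score map is permutation-equivariant", {
  model <- buildModel(gdmConfig(nConvLayers = 2, convChannels = 10,
                                attentionHeads = 5, seed = 21))
  g <- generateNetwork("barabasi_albert", 14, list(m = 2), seed = 6)
  s <- predictScores(model, g)
  set.seed(14)
  perm <- sample(0:13)
  gp <- g
  igraph::V(gp)$name <- as.character(perm[as.integer(igraph::V(g)$name) + 1L])
  sp <- predictScores(model, gp)
  for (oldId in 0:13) {
    expect_equal(unname(sp[as.character(perm[oldId + 1L])]),
                 unname(s[as.character(oldId)]))
  }
})

test_that("compiled forward and gradients match the R reference", {
  cfg <- gdmConfig(nConvLayers = 2, convChannels = 10, attentionHeads = 5,
                   regressorLayers = 2, regressorWidths = 20, seed = 7)
  model <- buildModel(cfg)
  g <- generateNetwork("erdos_renyi", 12, list(p = 0.3), seed = 4)
  X <- nodeFeatures(g)
  mask <- gdism:::.graphMask(g)
  pR <- gdism:::.gdmForward(model@params, X, mask, cfg,
                            training = FALSE, keepCache = FALSE)$p
  pC <- gdism:::cpp_gat_forward(model@params$conv, model@params$reg, X, mask,
                                cfg@convChannels, cfg@attentionHeads,
                                cfg@negativeSlope)
  expect_equal(unname(pR), as.numeric(pC), tolerance = 1e-12)

  set.seed(2)
  y <- runif(12)
  fw <- gdism:::.gdmForward(model@params, X, mask, cfg,
                            training = FALSE, keepCache = TRUE)
  gR <- gdism:::.flattenParams(gdism:::.gdmBackward(model@params, cfg, fw, y))
  gcpp <- gdism:::cpp_gat_grad(model@params$conv, model@params$reg, X, mask,
                               y, cfg@convChannels, cfg@attentionHeads,
                               cfg@negativeSlope)
  gC <- gdism:::.flattenParams(list(conv = gcpp$conv, reg = gcpp$reg))
  for (nm in names(gR)) {
    expect_equal(as.numeric(gR[[nm]]), as.numeric(gC[[nm]]),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- gdmConfig(nConvLayers = 2, convChannels = 5, attentionHeads = 5,
                   dropout = 0, regressorLayers = 1, regressorWidths = 20,
                   seed = 42)
  model <- buildModel(cfg)
  g <- generateNetwork("erdos_renyi", 8, list(p = 0.4), seed = 3)
  X <- nodeFeatures(g)
  mask <- gdism:::.graphMask(g)
  set.seed(9)
  y <- runif(8)
  params <- model@params
  fw <- gdism:::.gdmForward(params, X, mask, cfg, training = FALSE,
                            keepCache = TRUE)
  grads <- gdism:::.flattenParams(gdism:::.gdmBackward(params, cfg, fw, y))
  flat <- gdism:::.flattenParams(params)
  lossAt <- function(f2) {
    p2 <- gdism:::.fillParams(params, f2)
    mean((gdism:::.gdmForward(p2, X, mask, cfg, training = FALSE)$p - y)^2)
  }
  set.seed(1)
  h <- 1e-6
  for (nm in names(flat)) {
    v <- flat[[nm]]
    for (i in sample(length(v), min(2, length(v)))) {
      fp <- flat; fp[[nm]][i] <- v[i] + h
      fm <- flat; fm[[nm]][i] <- v[i] - h
      num <- (lossAt(fp) - lossAt(fm)) / (2 * h)
      expect_equal(as.numeric(grads[[nm]])[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and reduces the loss", {
  corpus <- buildTrainingCorpus(30, 12, generatorMix = c(star = 1),
                                targetFraction = 0.2, seed = 55)
  cfg <- tinyConfig(epochs = 8L, seed = 5L)
  m1 <- trainModel(buildModel(cfg), corpus)
  m2 <- trainModel(buildModel(cfg), corpus)
  expect_identical(m1@params, m2@params)
  loss <- attr(m1, "history")$loss
  expect_lt(loss[length(loss)], loss[1])
  expect_true(m1@trained)
  expect_error(trainModel(buildModel(cfg), list()), "empty corpus")
})

test_that("a star-trained model puts the hub on top of unseen stars", {
  corpus <- buildTrainingCorpus(100, c(9L, 11L, 13L), c(star = 1),
                                targetFraction = 0.2, seed = 71)
  model <- trainModel(buildModel(gdmConfig(nConvLayers = 2,
                                           convChannels = 10,
                                           attentionHeads = 5,
                                           regressorLayers = 1,
                                           regressorWidths = 20,
                                           epochs = 20, seed = 72)), corpus)
  for (i in 1:5) {
    g <- generateNetwork("star", 9 + 2 * i, seed = 9000 + i)
    expect_equal(names(which.max(predictScores(model, g))), "0")
  }
})

test_that("score of a node depends only on its L-hop neighborhood", {
  # 1 attention layer + degree feature: node 0 sees only itself and node 1,
  # so edits two hops away cannot change its score
  cfg <- gdmConfig(nConvLayers = 1, convChannels = 5, attentionHeads = 1,
                   regressorLayers = 1, regressorWidths = 20,
                   featureNames = "degree", seed = 31)
  model <- buildModel(cfg)
  g1 <- pathGraph(5)
  g2 <- igraph::add_edges(pathGraph(5), c("2", "4"))  # edit beyond 1-hop of 0
  s1 <- predictScores(model, g1)
  s2 <- predictScores(model, g2)
  expect_equal(unname(s1["0"]), unname(s2["0"]))
  expect_false(isTRUE(all.equal(unname(s1["3"]), unname(s2["3"]))))
})

test_that("checkpoints round-trip config and weights exactly", {
  corpus <- buildTrainingCorpus(10, 10, generatorMix = c(star = 1),
                                targetFraction = 0.2, seed = 61)
  model <- trainModel(buildModel(tinyConfig(epochs = 2L, seed = 6L)), corpus)
  f <- withr::local_tempfile()
  saveModel(model, f)
  back <- loadModel(f)
  expect_equal(model@params, back@params)
  expect_true(back@trained)
  g <- generateNetwork("erdos_renyi", 12, list(p = 0.3), seed = 9)
  expect_identical(predictScores(model, g), predictScores(back, g))
  bad <- withr::local_tempfile()
  writeLines("something_else=2", bad)
  expect_error(loadModel(bad), "version tag")
})

test_that("grid search selects by mean AUC with deterministic tie-breaks", {
  corpus <- buildTrainingCorpus(15, 10, generatorMix = c(star = 1),
                                targetFraction = 0.2, seed = 81)
  vg <- list(generateNetwork("erdos_renyi", 15, list(p = 0.25), seed = 91),
             generateNetwork("barabasi_albert", 15, list(m = 2), seed = 92))
  cfgA <- tinyConfig(epochs = 2L, seed = 3L)
  best <- gridSearchSelect(list(cfgA, cfgA), corpus, vg)
  sel <- attr(best, "selection")
  expect_equal(sel$meanAUC[1], sel$meanAUC[2])  # identical configs tie
  expect_true(sel$selected[1])                  # broken by earlier index
  expect_error(gridSearchSelect(list(), corpus, vg), "empty config")

  badCorpus <- buildTrainingCorpus(2, 8, generatorMix = c(star = 1),
                                   targetFraction = 0.25, seed = 82,
                                   featureNames = c("degree", "kcore"))
  expect_error(trainModel(buildModel(cfgA), badCorpus), "feature spec")
})
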