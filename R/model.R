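#' Create a model configuration
#'
#' See [GDMConfig-class] for the admissible hyperparameter grid. The shipped
#' default (3 attention layers of 30 channels with 10 concatenated heads and
#' a 2-layer regressor of width 40) sits inside that grid; dropout 0.3, the
#' LeakyReLU negative slope 0.2, learning rate 1e-5 and 50 training epochs
#' are the fixed training values of the method.
#'
#' @param nConvLayers number of graph-attention layers (1--4).
#' @param convChannels output channels per layer, recycled to `nConvLayers`.
#' @param attentionHeads concatenated attention heads.
#' @param dropout attention-coefficient dropout probability (training only).
#' @param negativeSlope LeakyReLU slope of the attention logits.
#' @param regressorLayers hidden layers of the regressor (1--4).
#' @param regressorWidths neurons per hidden layer, recycled.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialisation, sample order and
#'   dropout masks.
#' @param featureNames ordered input feature columns (see [nodeFeatures()]).
#' @return A validated [GDMConfig-class].
#' @export
gdmConfig <- function(nConvLayers = 3L, convChannels = 30L,
                      attentionHeads = 10L, dropout = 0.3,
                      negativeSlope = 0.2, regressorLayers = 2L,
                      regressorWidths = 40L, learningRate = 1e-5,
                      epochs = 50L, seed = 1L,
                      featureNames = c("degree", "chi2", "clustering",
                                       "kcore")) {
  new("GDMConfig",
      nConvLayers = as.integer(nConvLayers),
      convChannels = as.integer(rep_len(convChannels, nConvLayers)),
      attentionHeads = as.integer(attentionHeads),
      dropout = as.numeric(dropout),
      negativeSlope = as.numeric(negativeSlope),
      regressorLayers = as.integer(regressorLayers),
      regressorWidths = as.integer(rep_len(regressorWidths, regressorLayers)),
      learningRate = as.numeric(learningRate),
      epochs = as.integer(epochs),
      seed = as.integer(seed),
      featureNames = as.character(featureNames))
}

#' Build an (untrained) scoring model
#'
#' Instantiates the architecture: a stack of multi-head graph-attention
#' layers, each coupled with a node-wise linear layer of matching width whose
#' output is summed with the attention output before the ELU nonlinearity
#' (a residual-style shortcut), followed by a multilayer-perceptron regressor
#' whose sigmoid output constrains every node score to \[0, 1\]. The map is
#' permutation-equivariant and aggregates over the full neighborhood of every
#' node. Weights are Glorot-initialised from `config@seed`.
#'
#' @param config a [GDMConfig-class].
#' @return An untrained [GDMModel-class].
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "GDMConfig"))
  validObject(config)
  inputDim <- length(config@featureNames)
  set.seed(config@seed)
  new("GDMModel", config = config, params = .initParams(config, inputDim),
      trained = FALSE, inputDim = as.integer(inputDim))
}

# per-sample tensors reused across epochs
.sampleTensors <- function(sample, cfg) {
  feats <- sample@features
  if (!identical(colnames(feats), cfg@featureNames)) {
    stop("sample features (", paste(colnames(feats), collapse = ","),
         ") do not match the model feature spec (",
         paste(cfg@featureNames, collapse = ","), ")")
  }
  list(X = feats, mask = .graphMask(sample@graph),
       y = as.numeric(sample@labels[rownames(feats)]))
}

#' Train the scoring model
#'
#' Minimises the mean squared error between the predicted node scores and
#' the enumeration-derived labels with Adam, one graph per optimisation step
#' (full-batch over its nodes). Dropout on the attention coefficients is
#' active only during training. Runs are deterministic given the config
#' seed: initialisation, per-epoch sample order and dropout masks are all
#' drawn from it.
#'
#' @param model a [GDMModel-class] (typically from [buildModel()]).
#' @param corpus non-empty list of [TrainingSample-class] objects whose
#'   feature columns match the model's feature spec.
#' @param verbose print the mean training loss per epoch.
#' @return The trained model; `attr(model, "history")$loss` holds the mean
#'   training loss per epoch.
#' @export
trainModel <- function(model, corpus, verbose = FALSE) {
  stopifnot(is(model, "GDMModel"))
  if (length(corpus) == 0L) stop("empty corpus")
  cfg <- model@config
  tensors <- lapply(corpus, .sampleTensors, cfg = cfg)
  set.seed(as.integer(cfg@seed %% 2147483646L) + 1L)
  fit <- cpp_gat_train(model@params$conv, model@params$reg, tensors,
                       cfg@convChannels, cfg@attentionHeads,
                       cfg@negativeSlope, cfg@dropout, cfg@learningRate,
                       cfg@epochs)
  if (verbose) {
    for (epoch in seq_along(fit$loss)) {
      message(sprintf("epoch %3d  mean loss %.6f", epoch, fit$loss[epoch]))
    }
  }
  model@params <- .restoreShapes(model@params, list(conv = fit$conv,
                                                    reg = fit$reg))
  model@trained <- TRUE
  attr(model, "history") <- list(loss = as.numeric(fit$loss))
  model
}

# armadillo returns plain matrices; biases come back as column matrices and
# are restored to numeric vectors so the parameter tree keeps its shapes
.restoreShapes <- function(template, fitted) {
  .treeMap(function(tp, ft) {
    if (is.matrix(tp)) matrix(ft, nrow(tp), ncol(tp)) else as.numeric(ft)
  }, template, fitted)
}

#' Score the nodes of a graph
#'
#' Computes the model's input features on `g` (or uses a supplied feature
#' matrix, e.g., a single custom measure for heuristic enhancement) and runs
#' one forward pass. Scores are static: they are computed once on the intact
#' graph and never updated during an attack. Isolated nodes aggregate only
#' themselves and still receive a score.
#'
#' @param model a [GDMModel-class].
#' @param g igraph object.
#' @param features optional precomputed matrix from [nodeFeatures()] with
#'   columns matching the model's feature spec.
#' @return Named numeric vector of scores in \[0, 1\], one per node id.
#' @export
predictScores <- function(model, g, features = NULL) {
  stopifnot(is(model, "GDMModel"))
  g <- .ensureIds(g)
  if (is.null(features)) {
    features <- nodeFeatures(g, model@config@featureNames)
  }
  if (ncol(features) != model@inputDim) {
    stop("feature matrix has ", ncol(features), " columns; model expects ",
         model@inputDim)
  }
  cfg <- model@config
  p <- cpp_gat_forward(model@params$conv, model@params$reg, features,
                       .graphMask(g), cfg@convChannels, cfg@attentionHeads,
                       cfg@negativeSlope)
  stats::setNames(as.numeric(p), rownames(features))
}

#' Select the best configuration by validation dismantling
#'
#' Trains one model per configuration on the corpus, dismantles every
#' validation graph with the static ranked attack, and selects the
#' configuration with the lowest mean area under the LCC curve; exact ties
#' are broken by the smaller total number of removals, then by the earlier
#' configuration index.
#'
#' @param configs non-empty list of [GDMConfig-class] objects.
#' @param corpus training corpus (see [buildTrainingCorpus()]).
#' @param validationGraphs non-empty list of igraph objects.
#' @param targetFraction dismantling target for validation attacks
#'   (default 0.10).
#' @return The winning trained [GDMModel-class]; its `"selection"` attribute
#'   holds the per-config mean AUC and removal totals.
#' @export
gridSearchSelect <- function(configs, corpus, validationGraphs,
                             targetFraction = 0.1) {
  if (length(configs) == 0L) stop("empty config list")
  if (length(validationGraphs) == 0L) stop("no validation graphs")
  models <- vector("list", length(configs))
  meanAUC <- numeric(length(configs))
  totRemovals <- integer(length(configs))
  for (i in seq_along(configs)) {
    models[[i]] <- trainModel(buildModel(configs[[i]]), corpus)
    aucs <- numeric(length(validationGraphs))
    rem <- 0L
    for (j in seq_along(validationGraphs)) {
      vg <- .ensureIds(validationGraphs[[j]])
      tr <- staticAttack(vg, predictScores(models[[i]], vg), targetFraction)
      aucs[j] <- tr@auc
      rem <- rem + length(tr@removals)
    }
    meanAUC[i] <- mean(aucs)
    totRemovals[i] <- rem
  }
  best <- order(meanAUC, totRemovals, seq_along(configs))[1]
  out <- models[[best]]
  attr(out, "selection") <- data.frame(config = seq_along(configs),
                                       meanAUC = meanAUC,
                                       removals = totRemovals,
                                       selected = seq_along(configs) == best)
  out
}

#' Save and load a model checkpoint
#'
#' The checkpoint is a single plain-text file: a version tag, the
#' configuration as key=value lines, then one line per parameter array with
#' its name, dimensions and values at full double precision. Loading
#' reproduces the model exactly.
#'
#' @param model a [GDMModel-class].
#' @param path checkpoint file path.
#' @return `saveModel` invisibly returns `path`; `loadModel` returns the
#'   [GDMModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "GDMModel"))
  cfg <- model@config
  head <- c(
    "gdism_checkpoint=1",
    paste0("nConvLayers=", cfg@nConvLayers),
    paste0("convChannels=", paste(cfg@convChannels, collapse = ",")),
    paste0("attentionHeads=", cfg@attentionHeads),
    paste0("dropout=", format(cfg@dropout, digits = 17)),
    paste0("negativeSlope=", format(cfg@negativeSlope, digits = 17)),
    paste0("regressorLayers=", cfg@regressorLayers),
    paste0("regressorWidths=", paste(cfg@regressorWidths, collapse = ",")),
    paste0("learningRate=", format(cfg@learningRate, digits = 17)),
    paste0("epochs=", cfg@epochs),
    paste0("seed=", cfg@seed),
    paste0("featureNames=", paste(cfg@featureNames, collapse = ",")),
    paste0("trained=", model@trained))
  flat <- .flattenParams(model@params)
  body <- vapply(names(flat), function(nm) {
    v <- flat[[nm]]
    dims <- if (is.matrix(v)) c(nrow(v), ncol(v)) else c(length(v), 0L)
    paste(nm, dims[1], dims[2],
          paste(sprintf("%.17g", as.numeric(v)), collapse = " "))
  }, character(1))
  writeLines(c(head, body), path)
  invisible(path)
}

#' @rdname saveModel
#' @param path checkpoint file path.
#' @export
loadModel <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "gdism_checkpoint=1")) {
    stop("not a gdism checkpoint (unknown version tag)")
  }
  isKv <- grepl("^[A-Za-z]+=", lines)
  kvLines <- lines[isKv]
  kvPairs <- regmatches(kvLines, regexpr("=", kvLines), invert = TRUE)
  kv <- lapply(kvPairs, `[`, 2)
  names(kv) <- vapply(kvPairs, `[`, character(1), 1)
  cfg <- gdmConfig(
    nConvLayers = as.integer(kv$nConvLayers),
    convChannels = as.integer(strsplit(kv$convChannels, ",")[[1]]),
    attentionHeads = as.integer(kv$attentionHeads),
    dropout = as.numeric(kv$dropout),
    negativeSlope = as.numeric(kv$negativeSlope),
    regressorLayers = as.integer(kv$regressorLayers),
    regressorWidths = as.integer(strsplit(kv$regressorWidths, ",")[[1]]),
    learningRate = as.numeric(kv$learningRate),
    epochs = as.integer(kv$epochs),
    seed = as.integer(kv$seed),
    featureNames = strsplit(kv$featureNames, ",")[[1]])
  model <- buildModel(cfg)
  flat <- list()
  for (ln in lines[!isKv]) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    nm <- parts[1]
    vals <- as.numeric(parts[-(1:3)])
    flat[[nm]] <- vals
  }
  model@params <- .fillParams(model@params, flat)
  model@trained <- as.logical(kv$trained)
  model
}
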