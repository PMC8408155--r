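setOldClass("igraph")

#' Complete set of minimum dismantling sets of a small graph
#'
#' Produced by [bruteForceOptimalSets()]. Holds the LCC ceiling `targetSize`,
#' the minimum removal-set cardinality `k`, and every node set of size `k`
#' whose removal leaves all components at or below the ceiling.
#'
#' @slot targetSize integer LCC ceiling t.
#' @slot k integer, minimum removal-set cardinality.
#' @slot sets list of sorted integer node-id vectors, each of length `k`.
#' @slot nodes integer vector of all node ids of the source graph.
#' @slot graphId character identifier of the source graph.
#' @exportClass OptimalSolutionSet
setClass("OptimalSolutionSet",
  representation(targetSize = "integer", k = "integer", sets = "list",
                 nodes = "integer", graphId = "character"))

setValidity("OptimalSolutionSet", function(object) {
  if (length(object@sets) == 0L) return("'sets' must be non-empty")
  sizes <- lengths(object@sets)
  if (any(sizes != object@k)) return("every set must have exactly k nodes")
  keys <- vapply(object@sets, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) return("'sets' contains duplicates")
  if (!all(unlist(object@sets) %in% object@nodes)) {
    return("sets contain unknown node ids")
  }
  TRUE
})

setMethod("show", "OptimalSolutionSet", function(object) {
  cat(sprintf("OptimalSolutionSet: k = %d, %d optimal set(s), LCC target %d (graph %s, N = %d)\n",
              object@k, length(object@sets), object@targetSize,
              object@graphId, length(object@nodes)))
})

#' One labeled training network
#'
#' A small synthetic graph together with its per-node training labels (the
#' fraction of exhaustively enumerated optimal dismantling sets each node
#' belongs to), its node feature matrix, and generation provenance.
#'
#' @slot graph igraph object.
#' @slot labels named numeric vector in \[0, 1\], one entry per node.
#' @slot features numeric matrix, rows = nodes (rownames are node ids),
#'   columns = feature names.
#' @slot provenance list with generator name, parameters, seed, k and target.
#' @exportClass TrainingSample
setClass("TrainingSample",
  representation(graph = "igraph", labels = "numeric", features = "matrix",
                 provenance = "list"))

setValidity("TrainingSample", function(object) {
  ids <- as.character(sort(.nodeIds(object@graph)))
  if (!identical(sort(names(object@labels)), sort(ids))) {
    return("labels must cover exactly the nodes of the graph")
  }
  if (any(object@labels < 0 | object@labels > 1)) {
    return("labels must lie in [0, 1]")
  }
  if (nrow(object@features) != length(ids)) {
    return("feature matrix must have one row per node")
  }
  TRUE
})

setMethod("show", "TrainingSample", function(object) {
  cat(sprintf("TrainingSample: N = %d, E = %d, generator = %s, k = %s\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@provenance$generator %||% "?",
              format(object@provenance$k %||% NA)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Architecture and training configuration of the scoring model
#'
#' Values are restricted to the hyperparameter grid explored for this model
#' family: 1--4 attention layers with 5/10/20/30/40/50 output channels and
#' 1/5/10/15/20/30 concatenated heads, a 1--4 layer perceptron regressor
#' with 20/30/40/50/100 neurons per layer. Dropout (0.3), the LeakyReLU
#' negative slope of the attention logits (0.2), the learning rate (1e-5)
#' and the epoch count (50) default to the fixed training values.
#'
#' @slot nConvLayers integer, number of attention layers.
#' @slot convChannels integer vector, output channels per attention layer.
#' @slot attentionHeads integer, concatenated attention heads per layer.
#' @slot dropout numeric, attention-coefficient dropout probability.
#' @slot negativeSlope numeric, LeakyReLU slope of the attention logits.
#' @slot regressorLayers integer, hidden layers of the output perceptron.
#' @slot regressorWidths integer vector, neurons per hidden layer.
#' @slot learningRate numeric, Adam learning rate.
#' @slot epochs integer, training epochs.
#' @slot seed integer, seed fixing initialisation, sample order and dropout.
#' @slot featureNames character, ordered input feature columns.
#' @exportClass GDMConfig
setClass("GDMConfig",
  representation(nConvLayers = "integer", convChannels = "integer",
                 attentionHeads = "integer", dropout = "numeric",
                 negativeSlope = "numeric", regressorLayers = "integer",
                 regressorWidths = "integer", learningRate = "numeric",
                 epochs = "integer", seed = "integer",
                 featureNames = "character"))

.channelGrid <- c(5L, 10L, 20L, 30L, 40L, 50L)
.headGrid <- c(1L, 5L, 10L, 15L, 20L, 30L)
.widthGrid <- c(20L, 30L, 40L, 50L, 100L)

setValidity("GDMConfig", function(object) {
  if (object@nConvLayers < 1L || object@nConvLayers > 4L) {
    return("nConvLayers must be in 1..4")
  }
  if (length(object@convChannels) != object@nConvLayers) {
    return("convChannels must have one entry per attention layer")
  }
  if (!all(object@convChannels %in% .channelGrid)) {
    return("convChannels must be drawn from {5,10,20,30,40,50}")
  }
  if (!(object@attentionHeads %in% .headGrid)) {
    return("attentionHeads must be drawn from {1,5,10,15,20,30}")
  }
  if (object@regressorLayers < 1L || object@regressorLayers > 4L) {
    return("regressorLayers must be in 1..4")
  }
  if (length(object@regressorWidths) != object@regressorLayers) {
    return("regressorWidths must have one entry per regressor layer")
  }
  if (!all(object@regressorWidths %in% .widthGrid)) {
    return("regressorWidths must be drawn from {20,30,40,50,100}")
  }
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (length(object@featureNames) == 0L) return("featureNames must be non-empty")
  TRUE
})

setMethod("show", "GDMConfig", function(object) {
  cat(sprintf(paste0("GDMConfig: %d GAT layer(s) [channels %s, %d head(s)], ",
                     "regressor %s, dropout %.2f, lr %g, %d epochs, seed %d\n",
                     "  features: %s\n"),
              object@nConvLayers,
              paste(object@convChannels, collapse = "/"),
              object@attentionHeads,
              paste(object@regressorWidths, collapse = "/"),
              object@dropout, object@learningRate, object@epochs,
              object@seed, paste(object@featureNames, collapse = ", ")))
})

#' Graph-attention node-scoring model
#'
#' @slot config a [GDMConfig-class].
#' @slot params nested list of weight matrices (attention, linear shortcut
#'   and regressor layers, each with additive biases).
#' @slot trained logical flag.
#' @slot inputDim integer, number of input feature columns.
#' @exportClass GDMModel
setClass("GDMModel",
  representation(config = "GDMConfig", params = "list", trained = "logical",
                 inputDim = "integer"))

setMethod("show", "GDMModel", function(object) {
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("GDMModel (%s): %d parameters\n",
              if (object@trained) "trained" else "untrained", np))
  show(object@config)
})

#' Record of one dismantling attack
#'
#' `lcc` and `slcc` have length `length(removals) + 1`: entry 1 is the intact
#' graph, entry i+1 the state after the i-th removal. The area under the
#' LCC(x)/N curve is integrated by Simpson's rule over the removal index.
#'
#' @slot removals integer vector of removed node ids, in removal order.
#' @slot lcc,slcc integer vectors of component sizes along the attack.
#' @slot n0 integer, node count of the attacked graph.
#' @slot targetFraction numeric, LCC target as a fraction of `n0`.
#' @slot auc numeric, Simpson-rule area under LCC(x)/n0.
#' @exportClass DismantlingTrace
setClass("DismantlingTrace",
  representation(removals = "integer", lcc = "integer", slcc = "integer",
                 n0 = "integer", targetFraction = "numeric", auc = "numeric"))

setValidity("DismantlingTrace", function(object) {
  if (length(object@lcc) != length(object@removals) + 1L) {
    return("lcc must have one entry more than removals")
  }
  if (length(object@slcc) != length(object@lcc)) {
    return("slcc must match lcc in length")
  }
  if (any(diff(object@lcc) > 0L)) return("lcc must be non-increasing")
  t <- ceiling(object@targetFraction * object@n0)
  if (object@lcc[length(object@lcc)] > t) {
    return("final LCC exceeds the dismantling target")
  }
  TRUE
})

setMethod("show", "DismantlingTrace", function(object) {
  cat(sprintf(paste0("DismantlingTrace: %d removal(s) on N = %d, ",
                     "LCC %d -> %d (target <= %d), AUC = %.4f\n"),
              length(object@removals), object@n0, object@lcc[1],
              object@lcc[length(object@lcc)],
              ceiling(object@targetFraction * object@n0), object@auc))
})

#' Baseline of the early-warning statistic
#'
#' `sO` is the prefix of the model-driven static attack up to the collapse
#' point of the network (first peak of the second-largest component), and
#' `omegaM` the sum of the model scores over that set: the score mass the
#' system tolerates before it percolates.
#'
#' @slot sO integer vector of node ids, in removal order.
#' @slot omegaM numeric, sum of node scores over `sO`.
#' @slot scores named numeric vector of all node scores used.
#' @exportClass OmegaBaseline
setClass("OmegaBaseline",
  representation(sO = "integer", omegaM = "numeric", scores = "numeric"))

setValidity("OmegaBaseline", function(object) {
  if (object@omegaM < 0) return("omegaM must be non-negative")
  if (object@omegaM > length(object@sO) + 1e-9) {
    return("omegaM cannot exceed |sO| when scores are in [0, 1]")
  }
  TRUE
})

setMethod("show", "OmegaBaseline", function(object) {
  cat(sprintf("OmegaBaseline: |S_o| = %d, omega_m = %.4f\n",
              length(object@sO), object@omegaM))
})

#' Early-warning trajectory of an attack
#'
#' @slot removals integer vector of attacked node ids, in order.
#' @slot pi numeric, model score of each removed node.
#' @slot omegaS numeric, running sum of removed-node scores.
#' @slot omega numeric, normalised early warning in \[0, 1\].
#' @slot omegaPrime numeric, first difference of `omega`.
#' @slot lcc,slcc integer component sizes after each removal.
#' @slot omegaM numeric baseline score mass.
#' @slot collapseIndex integer, removal index of the first SLCC peak
#'   (NA for an empty attack).
#' @slot firstResponseTime integer, removals between the 0.5 warning
#'   crossing and the collapse (NA when the level is never reached).
#' @exportClass EarlyWarningTrace
setClass("EarlyWarningTrace",
  representation(removals = "integer", pi = "numeric", omegaS = "numeric",
                 omega = "numeric", omegaPrime = "numeric", lcc = "integer",
                 slcc = "integer", omegaM = "numeric",
                 collapseIndex = "integer", firstResponseTime = "integer"))

setValidity("EarlyWarningTrace", function(object) {
  n <- length(object@removals)
  if (length(object@omega) != n || length(object@pi) != n) {
    return("omega and pi must have one entry per removal")
  }
  if (n > 0L) {
    if (any(object@omega < -1e-12 | object@omega > 1 + 1e-12)) {
      return("omega must lie in [0, 1]")
    }
    if (any(diff(object@omega) < -1e-12)) return("omega must be non-decreasing")
  }
  TRUE
})

setMethod("show", "EarlyWarningTrace", function(object) {
  cat(sprintf(paste0("EarlyWarningTrace: %d removal(s), omega_m = %.4f, ",
                     "final omega = %s, collapse at %s, ",
                     "first response time = %s\n"),
              length(object@removals), object@omegaM,
              if (length(object@omega)) sprintf("%.4f", object@omega[length(object@omega)]) else "NA",
              format(object@collapseIndex), format(object@firstResponseTime)))
})
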