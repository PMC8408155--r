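#' Accessors for attack traces and solution sets
#'
#' `removals()` returns the ordered ids of removed nodes; `lccSizes()` and
#' `slccSizes()` the component-size series along an attack (for a
#' [DismantlingTrace-class] the first entry is the intact graph);
#' `aucValue()` the Simpson-rule area under the LCC curve; `optimalSets()`
#' the enumerated minimum dismantling sets and `optimalSize()` their common
#' cardinality k; `omegaSeries()` the early-warning values per removal;
#' `collapseIndex()` the removal index of the SLCC peak; `baselineMass()`
#' the score mass of the baseline set.
#'
#' @param x an object of the documented classes.
#' @return Vectors or scalars as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("removals", function(x) standardGeneric("removals"))
#' @rdname accessors
#' @export
setGeneric("lccSizes", function(x) standardGeneric("lccSizes"))
#' @rdname accessors
#' @export
setGeneric("slccSizes", function(x) standardGeneric("slccSizes"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("optimalSets", function(x) standardGeneric("optimalSets"))
#' @rdname accessors
#' @export
setGeneric("optimalSize", function(x) standardGeneric("optimalSize"))
#' @rdname accessors
#' @export
setGeneric("omegaSeries", function(x) standardGeneric("omegaSeries"))
#' @rdname accessors
#' @export
setGeneric("collapseIndex", function(x) standardGeneric("collapseIndex"))
#' @rdname accessors
#' @export
setGeneric("baselineMass", function(x) standardGeneric("baselineMass"))

#' @rdname accessors
setMethod("removals", "DismantlingTrace", function(x) x@removals)
#' @rdname accessors
setMethod("removals", "EarlyWarningTrace", function(x) x@removals)
#' @rdname accessors
setMethod("lccSizes", "DismantlingTrace", function(x) x@lcc)
#' @rdname accessors
setMethod("lccSizes", "EarlyWarningTrace", function(x) x@lcc)
#' @rdname accessors
setMethod("slccSizes", "DismantlingTrace", function(x) x@slcc)
#' @rdname accessors
setMethod("slccSizes", "EarlyWarningTrace", function(x) x@slcc)
#' @rdname accessors
setMethod("aucValue", "DismantlingTrace", function(x) x@auc)
#' @rdname accessors
setMethod("optimalSets", "OptimalSolutionSet", function(x) x@sets)
#' @rdname accessors
setMethod("optimalSize", "OptimalSolutionSet", function(x) x@k)
#' @rdname accessors
setMethod("omegaSeries", "EarlyWarningTrace", function(x) x@omega)
#' @rdname accessors
setMethod("collapseIndex", "EarlyWarningTrace", function(x) x@collapseIndex)
#' @rdname accessors
setMethod("baselineMass", "OmegaBaseline", function(x) x@omegaM)
#' @rdname accessors
setMethod("baselineMass", "EarlyWarningTrace", function(x) x@omegaM)

#' Write attack results to a directory
#'
#' Emits the CSV trace of a dismantling or early-warning object plus a flat
#' key=value manifest (package version, seed, summary statistics and any
#' extra configuration entries). Re-running with identical inputs reproduces
#' identical files.
#'
#' @param x a [DismantlingTrace-class] or [EarlyWarningTrace-class].
#' @param outDir output directory; created, must not exist unless
#'   `overwrite = TRUE`.
#' @param overwrite logical, allow writing into an existing directory.
#' @param config named list of extra configuration entries for the manifest.
#' @param seed optional integer recorded in the manifest.
#' @return Invisibly, the paths of the written files.
#' @export
setGeneric("writeResults",
  function(x, outDir, overwrite = FALSE, config = list(), seed = NULL)
    standardGeneric("writeResults"))
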