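# scores may come from a trained model or be supplied directly as a named
# numeric vector (e.g., a stub or an external scoring)
.resolveScores <- function(model, g) {
  if (is(model, "GDMModel")) return(predictScores(model, g))
  if (is.numeric(model) && !is.null(names(model))) return(model)
  stop("'model' must be a GDMModel or a named numeric score vector")
}

#' Early-warning baseline of a network
#'
#' Virtually dismantles `g` with the model's static ranked attack and takes
#' S_o, the prefix of the removal list up to (and including) the first peak
#' of the second-largest connected component -- the percolation point of the
#' attack. The baseline mass omega_m is the sum of the model scores over
#' S_o: the score mass the system tolerates before collapsing. With
#' `mode = "target"` S_o is instead the full removal list of the attack down
#' to the dismantling target.
#'
#' @param model a trained [GDMModel-class], or a named numeric score vector.
#' @param g igraph object with at least 3 nodes (the SLCC peak is undefined
#'   below that).
#' @param targetFraction dismantling target of the virtual attack
#'   (default 0.10).
#' @param mode `"slcc_peak"` (default) or `"target"`.
#' @return An [OmegaBaseline-class].
#' @export
computeBaseline <- function(model, g, targetFraction = 0.1,
                            mode = c("slcc_peak", "target")) {
  mode <- match.arg(mode)
  g <- .ensureIds(g)
  if (igraph::vcount(g) < 3L) {
    stop("graph must have at least 3 nodes for a defined SLCC peak")
  }
  scores <- .resolveScores(model, g)
  trace <- staticAttack(g, scores, targetFraction)
  if (length(trace@removals) == 0L) {
    stop("graph already satisfies the dismantling target; no baseline attack")
  }
  sO <- if (mode == "target") {
    trace@removals
  } else {
    slccAfter <- trace@slcc[-1]
    trace@removals[seq_len(which.max(slccAfter))]
  }
  new("OmegaBaseline", sO = as.integer(sO),
      omegaM = sum(scores[as.character(sO)]), scores = scores)
}

#' Early-warning value of a removal set
#'
#' The cumulative score mass omega_s of the removed nodes relative to the
#' baseline mass omega_m, clipped at 1: omega = omega_s / omega_m when
#' omega_s <= omega_m, and 1 otherwise.
#'
#' @param omegaS cumulative score of the removed nodes (>= 0); vectorised.
#' @param omegaM baseline score mass (> 0).
#' @return Values in \[0, 1\].
#' @examples
#' omegaValue(0.85, 1.7)  # 0.5
#' @export
omegaValue <- function(omegaS, omegaM) {
  if (!is.numeric(omegaM) || length(omegaM) != 1L || omegaM <= 0) {
    stop("omegaM must be a single positive number")
  }
  pmin(omegaS / omegaM, 1)
}

#' Early-warning trajectory of an attack
#'
#' Replays an arbitrary attack sequence on `g` and tracks, after each
#' removal: the removed node's score (PI), the running score sum omega_s,
#' the early warning omega = min(omega_s / omega_m, 1), its first difference
#' omega', and the LCC/SLCC sizes. The collapse index is the removal index
#' of the first SLCC peak of this attack, and the first response time is the
#' gap between the collapse and the first crossing of the warning level.
#'
#' @param model a trained [GDMModel-class] or a named numeric score vector.
#' @param g igraph object.
#' @param attack a [DismantlingTrace-class] produced on `g`, or an ordered
#'   vector of node ids; every node must exist in `g`.
#' @param baseline optional [OmegaBaseline-class]; computed from `model` and
#'   `g` when missing.
#' @param targetFraction target for the baseline attack when it has to be
#'   computed (default 0.10).
#' @param warningLevel omega level defining the first response time
#'   (default 0.5).
#' @return An [EarlyWarningTrace-class].
#' @export
omegaTrace <- function(model, g, attack, baseline = NULL,
                       targetFraction = 0.1, warningLevel = 0.5) {
  g <- .ensureIds(g)
  ids <- .nodeIds(g)
  seqIds <- if (is(attack, "DismantlingTrace")) attack@removals
            else as.integer(attack)
  if (!all(seqIds %in% ids)) stop("attack removes nodes absent from the graph")
  if (is.null(baseline)) {
    baseline <- computeBaseline(model, g, targetFraction)
  }
  scores <- if (is(model, "GDMModel")) baseline@scores
            else .resolveScores(model, g)
  n <- length(seqIds)
  if (n == 0L) {
    return(new("EarlyWarningTrace", removals = integer(0), pi = numeric(0),
               omegaS = numeric(0), omega = numeric(0),
               omegaPrime = numeric(0), lcc = integer(0), slcc = integer(0),
               omegaM = baseline@omegaM, collapseIndex = NA_integer_,
               firstResponseTime = NA_integer_))
  }
  pi <- as.numeric(scores[as.character(seqIds)])
  omegaS <- cumsum(pi)
  omega <- omegaValue(omegaS, baseline@omegaM)
  omegaPrime <- c(omega[1], diff(omega))
  h <- g
  lcc <- integer(n)
  slcc <- integer(n)
  for (i in seq_len(n)) {
    h <- .deleteIds(h, seqIds[i])
    sz <- .lccSlcc(h)
    lcc[i] <- sz[1]
    slcc[i] <- sz[2]
  }
  collapse <- which.max(slcc)
  tr <- new("EarlyWarningTrace", removals = seqIds, pi = pi, omegaS = omegaS,
            omega = omega, omegaPrime = omegaPrime,
            lcc = as.integer(lcc), slcc = as.integer(slcc),
            omegaM = baseline@omegaM, collapseIndex = as.integer(collapse),
            firstResponseTime = NA_integer_)
  tr@firstResponseTime <- firstResponseTime(tr, warningLevel)
  tr
}

#' First response time of an early-warning trajectory
#'
#' Number of removals between the first crossing of the warning level and
#' the collapse (SLCC peak): `collapseIndex - min(i: omega_i >= level)`.
#' Positive values mean the warning fired before the collapse; negative
#' values mean it fired after; NA when the level is never reached.
#'
#' @param trace an [EarlyWarningTrace-class].
#' @param warningLevel warning threshold in (0, 1\] (default 0.5).
#' @return Integer number of removals, or NA.
#' @export
firstResponseTime <- function(trace, warningLevel = 0.5) {
  stopifnot(is(trace, "EarlyWarningTrace"))
  if (!is.numeric(warningLevel) || length(warningLevel) != 1L ||
      warningLevel <= 0 || warningLevel > 1) {
    stop("warningLevel must lie in (0, 1]")
  }
  cross <- which(trace@omega >= warningLevel)
  if (length(cross) == 0L || is.na(trace@collapseIndex)) return(NA_integer_)
  as.integer(trace@collapseIndex - cross[1])
}

#' Articulation-point trace of an attack
#'
#' Before each removal (step 0 is the intact graph) counts the articulation
#' points of the current graph and how many of them still lie in the
#' not-yet-removed tail of the removal list. Articulation points are found
#' by the standard biconnected-components algorithm.
#'
#' @param g igraph object.
#' @param removalList ordered node ids, all present in `g`.
#' @return data.frame with columns `step` (0..length(removalList)), `nAp`
#'   and `nApInR`.
#' @export
apTrace <- function(g, removalList) {
  g <- .ensureIds(g)
  ids <- .nodeIds(g)
  removalList <- as.integer(removalList)
  if (!all(removalList %in% ids)) stop("removal list contains unknown nodes")
  n <- length(removalList)
  nAp <- integer(n + 1L)
  nApInR <- integer(n + 1L)
  h <- g
  for (i in 0:n) {
    aps <- as.integer(igraph::V(h)$name[igraph::articulation_points(h)])
    tail <- if (i < n) removalList[(i + 1L):n] else integer(0)
    nAp[i + 1L] <- length(aps)
    nApInR[i + 1L] <- length(intersect(aps, tail))
    if (i < n) h <- .deleteIds(h, removalList[i + 1L])
  }
  data.frame(step = 0:n, nAp = nAp, nApInR = nApInR)
}
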