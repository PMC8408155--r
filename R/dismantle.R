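# shared attack engine: visit nodes in a fixed ranking once, remove a node
# only if it currently belongs to the LCC, stop as soon as LCC <= t. A node
# skipped within a pass is not revisited in that pass; on tie-heavy
# symmetric graphs two equal components can alternate as the LCC so that a
# single pass exhausts the ranking above the target, in which case further
# passes over the still-present nodes (same order) run until the target is
# met -- every pass must remove at least one LCC member, so this terminates.
.rankedAttack <- function(g, ranking, targetFraction) {
  n0 <- igraph::vcount(g)
  t <- .stopTarget(targetFraction, n0)
  h <- g
  sizes <- .lccSlcc(h)
  lcc <- sizes[1]
  slcc <- sizes[2]
  removalsOut <- integer(0)
  done <- lcc[1] <= t
  while (!done) {
    for (v in setdiff(ranking, removalsOut)) {
      if (lcc[length(lcc)] <= t) break
      if (!(v %in% .lccMembers(h))) next
      h <- .deleteIds(h, v)
      sizes <- .lccSlcc(h)
      removalsOut <- c(removalsOut, v)
      lcc <- c(lcc, sizes[1])
      slcc <- c(slcc, sizes[2])
    }
    done <- lcc[length(lcc)] <= t
  }
  new("DismantlingTrace", removals = as.integer(removalsOut),
      lcc = as.integer(lcc), slcc = as.integer(slcc), n0 = as.integer(n0),
      targetFraction = targetFraction,
      auc = dismantlingAUC(lcc / n0))
}

#' Static score-ranked attack
#'
#' Nodes are visited once in descending score order (ties broken by
#' ascending node id). A visited node is removed only if it belongs to the
#' current largest connected component, otherwise it is skipped without
#' consuming a removal; the attack stops as soon as the LCC is at most
#' `ceiling(targetFraction * N)`. Scores are never recomputed: the method is
#' static by design.
#'
#' @param g igraph object.
#' @param scores named numeric vector covering every node id (e.g., from
#'   [predictScores()]).
#' @param targetFraction LCC target as a fraction of the node count
#'   (default 0.10).
#' @return A [DismantlingTrace-class].
#' @export
staticAttack <- function(g, scores, targetFraction = 0.1) {
  g <- .ensureIds(g)
  ids <- .nodeIds(g)
  if (!all(as.character(ids) %in% names(scores))) {
    stop("scores must cover every node of the graph")
  }
  s <- as.numeric(scores[as.character(ids)])
  ranking <- ids[order(-s, ids)]
  .rankedAttack(g, ranking, targetFraction)
}

#' Area under an LCC curve by Simpson's rule
#'
#' Integrates LCC(x)/N values over the removal index x = 0, 1, ..., R with
#' the composite Simpson rule; when the number of intervals is odd the last
#' panel is handled by the trapezoid rule. A single value has zero-width
#' support and integrates to 0.
#'
#' @param lccFractions numeric vector of LCC sizes divided by the node
#'   count, in removal order (first entry = intact graph).
#' @return The integral as a single number.
#' @examples
#' dismantlingAUC(c(1, 0.5, 0.25))  # (1/3) * (1 + 4 * 0.5 + 0.25)
#' @export
dismantlingAUC <- function(lccFractions) {
  v <- as.numeric(lccFractions)
  if (length(v) == 0L) stop("empty LCC curve")
  if (any(v < 0 | v > 1)) stop("LCC fractions must lie in [0, 1]")
  n <- length(v)
  if (n == 1L) return(0)
  m <- n - 1L  # intervals of unit width
  total <- 0
  if (m %% 2L == 1L && m > 1L) {
    total <- total + (v[n - 1L] + v[n]) / 2
    v <- v[seq_len(n - 1L)]
    n <- n - 1L
    m <- m - 1L
  } else if (m == 1L) {
    return((v[1] + v[2]) / 2)
  }
  i <- seq(1L, n - 2L, by = 2L)
  total + sum(v[i] + 4 * v[i + 1L] + v[i + 2L]) / 3
}

#' Greedy reinsertion of unnecessary removals
#'
#' After a (virtual) dismantling, some removed nodes turn out not to be
#' needed to hold the LCC below the target: putting them back (with all
#' their edges towards currently present nodes) keeps every component at or
#' below `ceiling(targetFraction * N)`. Those nodes are reinserted greedily,
#' smallest post-reinsertion component first (ties broken by ascending node
#' id), until no further single reinsertion is feasible, so the remaining
#' removal set is minimal with respect to single reinsertions.
#'
#' @param g the graph the trace was produced on.
#' @param trace a [DismantlingTrace-class] from an attack on `g`.
#' @return A new [DismantlingTrace-class] whose removal list is a subset of
#'   the input's (original order), with the LCC/SLCC series and AUC replayed
#'   on the pruned list.
#' @export
greedyReinsertion <- function(g, trace) {
  stopifnot(is(trace, "DismantlingTrace"))
  g <- .ensureIds(g)
  ids <- .nodeIds(g)
  if (igraph::vcount(g) != trace@n0 || !all(trace@removals %in% ids)) {
    stop("trace does not match the supplied graph")
  }
  t <- .stopTarget(trace@targetFraction, trace@n0)
  removed <- trace@removals
  repeat {
    best <- NULL
    bestSize <- Inf
    for (r in sort(removed)) {
      present <- setdiff(ids, setdiff(removed, r))
      h <- igraph::induced_subgraph(g, as.character(present))
      if (.lccSize(h) > t) next
      cmp <- igraph::components(h)
      rSize <- cmp$csize[cmp$membership[as.character(r)]]
      if (rSize < bestSize) {
        best <- r
        bestSize <- rSize
      }
    }
    if (is.null(best)) break
    removed <- setdiff(removed, best)
  }
  kept <- trace@removals[trace@removals %in% removed]
  .replayRemovals(g, kept, trace@targetFraction)
}

# rebuild a trace by removing a fixed list of nodes in order
.replayRemovals <- function(g, removalList, targetFraction) {
  n0 <- igraph::vcount(g)
  h <- g
  sizes <- .lccSlcc(h)
  lcc <- sizes[1]
  slcc <- sizes[2]
  for (v in removalList) {
    h <- .deleteIds(h, v)
    sizes <- .lccSlcc(h)
    lcc <- c(lcc, sizes[1])
    slcc <- c(slcc, sizes[2])
  }
  new("DismantlingTrace", removals = as.integer(removalList),
      lcc = as.integer(lcc), slcc = as.integer(slcc), n0 = as.integer(n0),
      targetFraction = targetFraction, auc = dismantlingAUC(lcc / n0))
}

#' Centrality-based baseline attacks
#'
#' Ranks nodes by degree or betweenness (the `inverse_*` strategies attack
#' in ascending order, i.e., peripheral nodes first) and applies the same
#' LCC-membership skip rule and stop condition as [staticAttack()]. With
#' `recompute = TRUE` the centrality is recomputed on the current graph
#' after every removal and the next removal is the extreme-centrality node
#' of the current LCC, which is the classic dynamic heuristic used in attack
#' experiments.
#'
#' @param g igraph object.
#' @param strategy one of `"degree"`, `"betweenness"`, `"inverse_degree"`,
#'   `"inverse_betweenness"`.
#' @param targetFraction LCC target fraction (default 0.10).
#' @param recompute logical, re-rank after every removal.
#' @return A [DismantlingTrace-class].
#' @export
heuristicAttack <- function(g, strategy = c("degree", "betweenness",
                                            "inverse_degree",
                                            "inverse_betweenness"),
                            targetFraction = 0.1, recompute = FALSE) {
  strategy <- match.arg(strategy)
  g <- .ensureIds(g)
  base <- sub("^inverse_", "", strategy)
  sign <- if (grepl("^inverse_", strategy)) 1 else -1
  centrality <- function(h) {
    v <- switch(base,
                degree = igraph::degree(h),
                betweenness = igraph::betweenness(h, directed = FALSE))
    stats::setNames(as.numeric(v), igraph::V(h)$name)
  }
  if (!recompute) {
    ids <- .nodeIds(g)
    cv <- centrality(g)[as.character(ids)]
    ranking <- ids[order(sign * cv, ids)]
    return(.rankedAttack(g, ranking, targetFraction))
  }
  n0 <- igraph::vcount(g)
  t <- .stopTarget(targetFraction, n0)
  h <- g
  sizes <- .lccSlcc(h)
  lcc <- sizes[1]
  slcc <- sizes[2]
  removalsOut <- integer(0)
  while (lcc[length(lcc)] > t) {
    members <- .lccMembers(h)
    cv <- centrality(h)[as.character(members)]
    v <- members[order(sign * cv, members)][1]
    h <- .deleteIds(h, v)
    sizes <- .lccSlcc(h)
    removalsOut <- c(removalsOut, v)
    lcc <- c(lcc, sizes[1])
    slcc <- c(slcc, sizes[2])
  }
  new("DismantlingTrace", removals = as.integer(removalsOut),
      lcc = as.integer(lcc), slcc = as.integer(slcc), n0 = as.integer(n0),
      targetFraction = targetFraction, auc = dismantlingAUC(lcc / n0))
}
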