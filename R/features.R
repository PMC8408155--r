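#' Neighborhood chi-squared degree statistic
#'
#' For node v with neighbors Nb(v), let d-bar be the mean degree over Nb(v);
#' the statistic is the Pearson-style sum of (deg(u) - d-bar)^2 / d-bar over
#' the neighbors u. It is large for nodes whose neighborhood mixes very
#' different degrees (e.g., a bridge between a hub and a periphery) and 0
#' for isolated nodes, degree-1 nodes and nodes with degree-homogeneous
#' neighborhoods such as the hub of a star.
#'
#' @param g igraph object.
#' @return Named numeric vector (>= 0), one entry per node id.
#' @export
neighborhoodChi2 <- function(g) {
  g <- .ensureIds(g)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  chi2 <- vapply(adj, function(nb) {
    if (length(nb) == 0L) return(0)
    dn <- deg[as.integer(nb)]
    dbar <- mean(dn)
    if (dbar == 0) return(0)
    sum((dn - dbar)^2 / dbar)
  }, numeric(1))
  names(chi2) <- igraph::V(g)$name
  chi2
}

#' Per-node input features of the scoring model
#'
#' The default feature set combines a local signal (node degree and the
#' chi-squared statistic of the neighborhood degrees), a second-order signal
#' (local clustering coefficient, 0 for nodes of degree < 2) and a global
#' signal (k-core number from iterative degree peeling). Any node measure can
#' stand in as a custom column, which allows an existing heuristic (e.g.,
#' betweenness) to be used as the only input of the model.
#'
#' @param g igraph object.
#' @param features character vector naming built-in columns (`"degree"`,
#'   `"chi2"`, `"clustering"`, `"kcore"`), or a named list mixing built-in
#'   names (as character entries) and numeric per-node vectors (custom
#'   measures, named by node id or aligned with sorted node ids).
#' @param rescale logical; min-max rescale each column to \[0, 1\] within the
#'   network (off by default).
#' @return Numeric matrix with one row per node (rownames = node ids, sorted)
#'   and one column per feature, all values finite.
#' @examples
#' nodeFeatures(generateNetwork("star", 5, seed = 1), "degree")
#' @export
nodeFeatures <- function(g, features = c("degree", "chi2", "clustering",
                                         "kcore"),
                         rescale = FALSE) {
  g <- .ensureIds(g)
  if (length(features) == 0L) stop("features must be non-empty")
  ids <- sort(.nodeIds(g))
  key <- as.character(ids)
  builtin <- function(name) {
    v <- switch(name,
      degree = igraph::degree(g),
      chi2 = neighborhoodChi2(g),
      clustering = {
        cc <- igraph::transitivity(g, type = "local", isolates = "zero")
        names(cc) <- igraph::V(g)$name
        cc[is.na(cc)] <- 0
        cc
      },
      kcore = igraph::coreness(g),
      stop("unknown feature name: ", name))
    if (is.null(names(v))) names(v) <- igraph::V(g)$name
    v[key]
  }
  if (!is.list(features)) features <- as.list(features)
  if (is.null(names(features))) {
    names(features) <- vapply(features, function(f)
      if (is.character(f)) f else "custom", character(1))
  }
  cols <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    if (is.character(f) && length(f) == 1L) return(builtin(f))
    if (!is.numeric(f) || length(f) != length(ids)) {
      stop("custom feature '", names(features)[i],
           "' must be numeric with one value per node")
    }
    if (!is.null(names(f))) f[key] else f
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(key, names(features))
  if (any(!is.finite(m))) stop("non-finite feature values")
  if (rescale) {
    m <- apply(m, 2, function(x) {
      r <- range(x)
      if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
    })
    dimnames(m) <- list(key, names(features))
  }
  m
}

#' Export a feature matrix as TSV
#'
#' @param features matrix from [nodeFeatures()].
#' @param path output file; a header row names the node-id column and the
#'   feature columns.
#' @return Invisibly, `path`.
#' @export
writeFeatures <- function(features, path) {
  df <- data.frame(node = rownames(features), features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
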