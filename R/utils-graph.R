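# Internal helpers around igraph. Graphs carry their external node ids in
# the vertex `name` attribute (stored as characters of integers); all
# user-facing functions speak in those ids, never in igraph vertex indices.

.ensureIds <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  }
  g
}

.nodeIds <- function(g) {
  ids <- suppressWarnings(as.integer(igraph::V(g)$name))
  if (anyNA(ids)) stop("graph vertex names must be integer node ids")
  ids
}

# largest and second-largest component sizes; a graph with a single
# component has SLCC 0, an empty graph has LCC 0
.lccSlcc <- function(g) {
  if (igraph::vcount(g) == 0L) return(c(0L, 0L))
  sz <- sort(igraph::components(g)$csize, decreasing = TRUE)
  c(sz[1], if (length(sz) > 1L) sz[2] else 0L)
}

.lccSize <- function(g) .lccSlcc(g)[1]

# ids of the nodes currently in the largest component (ties broken by
# igraph's component order; only membership is ever used)
.lccMembers <- function(g) {
  cmp <- igraph::components(g)
  keep <- which.max(cmp$csize)
  .nodeIds(g)[cmp$membership == keep]
}

.deleteIds <- function(g, ids) {
  igraph::delete_vertices(g, as.character(ids))
}

# 0-based edge matrix indexed by position in `ids` (sorted external ids),
# for the compiled union-find routines
.edgeMatrix0 <- function(g, ids = sort(.nodeIds(g))) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(matrix(integer(0), 0, 2))
  cbind(match(as.integer(el[, 1]), ids) - 1L,
        match(as.integer(el[, 2]), ids) - 1L)
}

.stopTarget <- function(targetFraction, n) {
  if (!is.numeric(targetFraction) || length(targetFraction) != 1L ||
      targetFraction <= 0 || targetFraction >= 1) {
    stop("targetFraction must be a single number in (0, 1)")
  }
  as.integer(ceiling(targetFraction * n))
}

# flat key=value text block used by manifests and checkpoints
.writeKeyValues <- function(x, path) {
  vals <- vapply(x, function(v) paste(format(v, digits = 17), collapse = ","),
                 character(1))
  writeLines(paste0(names(x), "=", vals), path)
}

.readKeyValues <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}
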