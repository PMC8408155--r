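#' Read an undirected simple graph from a whitespace edge list
#'
#' Each non-comment line must start with two integer node ids; further
#' columns (e.g., weights) are ignored. Lines starting with `#` or `%` are
#' skipped. Self-loops and duplicate edges (in either orientation) are
#' dropped with a message, and any direction encoded in the file is
#' discarded: the result is an undirected simple graph over the integers
#' appearing in the first two columns.
#'
#' @param path edge-list file.
#' @return igraph object with the original ids as vertex names.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#%]", lines)]
  if (length(lines) == 0L) stop("no edges in file: ", path)
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(tok) < 2L)
  if (length(bad)) stop("line ", bad[1], " has fewer than two columns")
  u <- suppressWarnings(as.integer(vapply(tok, `[`, character(1), 1)))
  v <- suppressWarnings(as.integer(vapply(tok, `[`, character(1), 2)))
  if (anyNA(u) || anyNA(v)) stop("non-integer node id in edge list")
  loops <- u == v
  a <- pmin(u, v)[!loops]
  b <- pmax(u, v)[!loops]
  dup <- duplicated(cbind(a, b))
  if (any(loops) || any(dup)) {
    message(sum(loops), " self-loop(s) and ", sum(dup),
            " duplicate edge(s) dropped from ", basename(path))
  }
  a <- a[!dup]
  b <- b[!dup]
  ids <- sort(unique(c(u, v)))
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(match(a, ids), match(b, ids)))
  }
  g
}

#' Write a graph as a whitespace edge list
#'
#' @param g igraph object.
#' @param path output file, one "u v" line per edge.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(g, path) {
  g <- .ensureIds(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

.prepareOutDir <- function(outDir, overwrite) {
  if (dir.exists(outDir) && !overwrite) {
    stop("output directory exists; use overwrite = TRUE")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
}

.manifest <- function(extra, config, seed) {
  c(list(tool = "gdism", version = as.character(utils::packageVersion("gdism")),
         seed = if (is.null(seed)) NA else seed),
    config, extra)
}

#' @rdname writeResults
setMethod("writeResults", "DismantlingTrace",
  function(x, outDir, overwrite = FALSE, config = list(), seed = NULL) {
    .prepareOutDir(outDir, overwrite)
    n <- length(x@removals)
    df <- data.frame(removal_index = seq_len(n), node_id = x@removals,
                     lcc_size = x@lcc[-1], slcc_size = x@slcc[-1])
    tracePath <- file.path(outDir, "trace.csv")
    utils::write.csv(df, tracePath, row.names = FALSE, quote = FALSE)
    manifestPath <- file.path(outDir, "manifest.txt")
    .writeKeyValues(.manifest(list(
      n0 = x@n0, target_fraction = x@targetFraction,
      initial_lcc = x@lcc[1], initial_slcc = x@slcc[1],
      removals = n, auc = x@auc), config, seed), manifestPath)
    invisible(c(tracePath, manifestPath))
  })

#' @rdname writeResults
setMethod("writeResults", "EarlyWarningTrace",
  function(x, outDir, overwrite = FALSE, config = list(), seed = NULL) {
    .prepareOutDir(outDir, overwrite)
    n <- length(x@removals)
    df <- data.frame(removal_index = seq_len(n), node_id = x@removals,
                     pi = x@pi, omega_s = x@omegaS, omega = x@omega,
                     omega_prime = x@omegaPrime, lcc = x@lcc, slcc = x@slcc)
    tracePath <- file.path(outDir, "early_warning.csv")
    utils::write.csv(df, tracePath, row.names = FALSE, quote = FALSE)
    manifestPath <- file.path(outDir, "manifest.txt")
    .writeKeyValues(.manifest(list(
      omega_m = x@omegaM, removals = n,
      collapse_index = x@collapseIndex,
      first_response_time = x@firstResponseTime), config, seed), manifestPath)
    invisible(c(tracePath, manifestPath))
  })
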