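# Interaction graph construction and topology: degree, betweenness, and
# shortest-path reporting. Combined scores gate edge existence only; path
# lengths are hop counts.

#' Build an undirected simple interaction graph
#'
#' Collapses duplicate undirected edges (keeping the maximum score), drops
#' self-loops, and optionally restricts nodes to a supplied universe (e.g.
#' the bridge proteins), retaining isolated universe nodes. Edges with an
#' endpoint outside the universe are dropped and counted.
#'
#' @param edges data.frame `protein1`, `protein2`, `combined_score`.
#' @param node_universe optional character vector of allowed nodes.
#' @return an `igraph` graph with edge attribute `combined_score` and
#'   attribute `dropped_edges` (count removed by the restriction).
#' @export
build_graph <- function(edges, node_universe = NULL) {
  stopifnot(all(c("protein1", "protein2") %in% names(edges)))
  dropped <- 0L
  if (!is.null(node_universe)) {
    keep <- edges$protein1 %in% node_universe & edges$protein2 %in% node_universe
    dropped <- sum(!keep)
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("protein1", "protein2", "combined_score")],
    directed = FALSE,
    vertices = if (is.null(node_universe)) NULL else unique(node_universe))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(combined_score = "max"))
  g <- igraph::set_graph_attr(g, "dropped_edges", dropped)
  g
}

#' Degree centrality (incident edge counts)
#'
#' @param graph an `igraph` graph.
#' @return named integer vector.
#' @export
degree_centrality <- function(graph) {
  d <- igraph::degree(graph, loops = FALSE)
  stats::setNames(as.integer(d), names(d))
}

#' Betweenness centrality (unnormalized shortest-path pair counts)
#'
#' For each unordered node pair (s, t), every interior node v of their
#' shortest paths accrues `sigma_st(v) / sigma_st`, the fraction of shortest
#' s-t paths through v, accumulated over breadth-first shortest-path DAGs.
#' Unweighted: combined scores are ignored for path length.
#'
#' @param graph an `igraph` graph.
#' @return named numeric vector of raw pair counts.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Combined per-node centrality table
#'
#' @param graph an `igraph` graph.
#' @return data.frame `node`, `degree`, `betweenness`,
#'   `betweenness_normalized` (divided by `(n-1)(n-2)/2`).
#' @export
centrality_table <- function(graph) {
  deg <- degree_centrality(graph)
  btw <- betweenness_centrality(graph)
  n <- igraph::vcount(graph)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  df <- data.frame(node = names(deg), degree = unname(deg),
                   betweenness = unname(btw[names(deg)]),
                   betweenness_normalized = unname(btw[names(deg)]) / denom,
                   stringsAsFactors = FALSE)
  df[order(-df$betweenness, -df$degree, df$node), , drop = FALSE]
}

#' All shortest paths between two proteins
#'
#' Breadth-first (hop-count) shortest paths. A disconnected pair yields an
#' explicit no-path result rather than an error.
#'
#' @param graph an `igraph` graph.
#' @param source,target node names.
#' @param max_paths cap on the number of reported paths (default 100).
#' @return list: `length` (hops; 0 for source = target; `Inf` when
#'   disconnected), `paths` (list of node-name vectors), `truncated`.
#' @export
shortest_paths_between <- function(graph, source, target, max_paths = 100) {
  vn <- igraph::V(graph)$name
  if (!(source %in% vn)) stop("source not in graph: ", source)
  if (!(target %in% vn)) stop("target not in graph: ", target)
  if (source == target)
    return(list(length = 0, paths = list(source), truncated = FALSE))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(graph, from = source, to = target, weights = NA))
  paths <- lapply(sp$res, function(p) igraph::as_ids(p))
  if (length(paths) == 0)
    return(list(length = Inf, paths = list(), truncated = FALSE))
  truncated <- length(paths) > max_paths
  if (truncated) paths <- paths[seq_len(max_paths)]
  list(length = length(paths[[1]]) - 1L, paths = paths, truncated = truncated)
}
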