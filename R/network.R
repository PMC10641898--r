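#' Build a state-specific functional connectivity graph
#'
#' One node per recorded cell (isolated cells are kept: they enter the node
#' count and the network mean with centrality zero); one undirected edge per
#' pair classified `correlated`, weighted by the pair's Pearson correlation in
#' the graph's state. Duplicate pairs collapse to a single edge; weights are
#' clipped into (0, 1) so that edge lengths `log(1/w)` stay positive and
#' finite.
#'
#' @param pairs A `pair_results` data frame for one state scope.
#' @param n_cells Number of recorded cells (nodes); defaults to the largest
#'   cell id seen in `pairs`.
#' @param state Optional state label stored on the graph.
#' @return An `igraph` undirected graph with edge attribute `weight`.
#' @export
build_graph <- function(pairs, n_cells = NULL, state = NULL) {
  ed <- pairs[pairs$klass == "correlated", c("i", "j", "r"), drop = FALSE]
  if (is.null(n_cells)) {
    n_cells <- if (nrow(pairs)) max(pairs$i, pairs$j) else 0L
  }
  key <- paste(pmin(ed$i, ed$j), pmax(ed$i, ed$j))
  ed <- ed[!duplicated(key), , drop = FALSE]
  w <- pmin(pmax(ed$r, 1e-12), 1 - 1e-9)
  g <- igraph::make_empty_graph(n = n_cells, directed = FALSE)
  if (nrow(ed)) {
    g <- igraph::add_edges(g, rbind(ed$i, ed$j), weight = w)
  }
  if (!is.null(state)) g <- igraph::set_graph_attr(g, "state", state)
  g
}

#' Normalized weighted closeness centrality
#'
#' Edge lengths are `d(i, j) = log(1 / w_ij)` (natural log by default) so that
#' strong correlations are short. For each node the weighted shortest-path
#' distances to all reachable nodes are summed (`C_i`); with `A_i` reachable
#' nodes out of `N - 1`, the closeness is
#' \deqn{c(i) = (A_i / (N - 1))^2 / C_i,}
#' and an isolated node scores 0. The network-level value is the node mean
#' multiplied by the node count (equivalently, the sum of the `c_i`), which
#' normalizes across networks of different sizes.
#'
#' @param g An `igraph` graph from [build_graph()] with `weight` in (0, 1).
#' @param log_base `"e"` (default) or `"10"`: base of the distance transform.
#' @return A `centrality_result` list: `nodes` (data frame `node`, `A`, `C`,
#'   `c`), `network_mean`, `n_nodes`, `state`.
#' @export
closeness_centrality <- function(g, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  N <- igraph::vcount(g)
  if (N < 2L) stop("closeness_centrality: need at least 2 nodes")
  w <- igraph::E(g)$weight
  if (length(w) && (any(w <= 0) || any(w >= 1))) {
    stop("closeness_centrality: edge weights must lie strictly in (0, 1)")
  }
  d <- if (log_base == "e") log(1 / w) else log10(1 / w)
  D <- igraph::distances(g, weights = if (length(w)) d else NA)
  A <- integer(N); C <- numeric(N); cvals <- numeric(N)
  for (i in seq_len(N)) {
    dist_i <- D[i, -i]
    reach <- is.finite(dist_i)
    A[i] <- sum(reach)
    C[i] <- sum(dist_i[reach])
    cvals[i] <- if (A[i] == 0L) 0 else (A[i] / (N - 1))^2 / C[i]
  }
  out <- list(
    nodes = data.frame(node = seq_len(N), A = A, C = C, c = cvals),
    network_mean = sum(cvals),
    n_nodes = N,
    state = igraph::graph_attr(g, "state")
  )
  class(out) <- "centrality_result"
  out
}

#' @export
print.centrality_result <- function(x, ...) {
  st <- if (is.null(x$state)) "" else sprintf(" [%s]", x$state)
  cat(sprintf(
    "Closeness centrality%s: %d nodes, network mean (normalized) = %.4f\n",
    st, x$n_nodes, x$network_mean
  ))
  invisible(x)
}

#' Network-level normalized closeness
#'
#' Mean node closeness multiplied by the node count (equal to the sum of the
#' per-node values).
#'
#' @param result A `centrality_result` (or an `igraph` graph, in which case
#'   centrality is computed first).
#' @param ... Passed to [closeness_centrality()] when `result` is a graph.
#' @return Scalar network closeness.
#' @export
network_mean <- function(result, ...) {
  if (inherits(result, "igraph")) result <- closeness_centrality(result, ...)
  result$network_mean
}

#' Rest-minus-run difference in network closeness
#'
#' @param rest,run `centrality_result` objects (or graphs) for the resting and
#'   running networks of the same session's cells.
#' @param ... Passed to [closeness_centrality()] for graph inputs.
#' @return `network_mean(rest) - network_mean(run)`; positive values indicate
#'   desynchronization during locomotion.
#' @export
centrality_difference <- function(rest, run, ...) {
  network_mean(rest, ...) - network_mean(run, ...)
}

#' Write a weighted edge list as TSV
#'
#' @param g An `igraph` graph with a `weight` edge attribute.
#' @param path Output file path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(i = el[, 1], j = el[, 2],
                   w = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
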