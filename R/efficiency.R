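#' Geodesic distance matrix of a binary graph
#'
#' Unweighted shortest-path lengths between all node pairs; unreachable
#' pairs are `Inf` (a true sentinel, never a large finite stand-in, so that
#' their efficiency contribution is exactly zero).
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @return An `N x N` matrix of nonnegative integers / `Inf`, zero diagonal.
#' @export
shortest_paths <- function(g) {
  a <- as.matrix(unclass(g))
  validate_adjacency(a)
  gr <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(gr)
  dimnames(d) <- dimnames(a)
  d
}

#' Pair efficiency
#'
#' The efficiency of communication between two nodes is the reciprocal of
#' their geodesic distance, and zero when no path connects them.
#'
#' @param d Geodesic distance(s): positive values or `Inf` (vectorized).
#' @return `1/d`, with `Inf -> 0`.
#' @export
pair_efficiency <- function(d) {
  if (any(d == 0, na.rm = TRUE))
    stop("pair efficiency is undefined at distance 0 (distinct nodes ",
         "cannot be at distance 0)")
  ifelse(is.infinite(d), 0, 1 / d)
}

# Mean of 1/d over ordered off-diagonal pairs of a distance matrix.
efficiency_from_dist <- function(d) {
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  sum(ifelse(is.infinite(off), 0, 1 / off)) / (n * (n - 1))
}

#' Global efficiency
#'
#' The network's efficiency `Sigma(G)`: the average of the pair efficiency
#' `1/d_ij` over all `N(N-1)` ordered node pairs.  It is 1 exactly for the
#' complete graph and 0 for the edgeless graph, and unreachable pairs
#' contribute 0.
#'
#' @param g A `group_adjacency` or binary adjacency matrix with `N >= 2`.
#' @return A number in `[0, 1]`.
#' @examples
#' global_efficiency(matrix(1, 4, 4) - diag(4))  # complete K4 -> 1
#' @export
global_efficiency <- function(g) {
  a <- as.matrix(unclass(g))
  if (nrow(a) < 2)
    stop("global efficiency requires at least 2 nodes")
  efficiency_from_dist(shortest_paths(a))
}

lesion_result <- function(baseline, lesioned, lesion, mode) {
  structure(list(baseline = baseline, lesioned = lesioned,
                 loss = (baseline - lesioned) / baseline,
                 lesion = lesion, mode = mode),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> %s [%s]: Sigma %.4f -> %.4f, loss %.2f%%\n",
              x$lesion, x$mode, x$baseline, x$lesioned, 100 * x$loss))
  invisible(x)
}

#' Information centrality of a node
#'
#' The efficiency loss caused by lesioning node `i`: the relative drop in
#' global efficiency between the intact graph and the graph with the
#' lesion applied, `C_i = (Sigma(G) - Sigma(G')) / Sigma(G)`.
#'
#' Two lesioning semantics are provided.  The default, `"isolate"`, deletes
#' every edge incident to `i` but keeps all `N` nodes (the node becomes
#' unreachable), which is the information-centrality convention of Latora
#' and Marchiori; `C_i` then lies in `[0, 1]`.  `"remove"` deletes the node
#' itself and renormalizes over `(N-1)(N-2)` ordered pairs; it is offered
#' for sensitivity analysis and can in principle be negative.
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @param i Node index.
#' @param mode `"isolate"` (default) or `"remove"`.
#' @return A `lesion_result` with `baseline`, `lesioned`, `loss`, `mode`.
#' @export
node_centrality <- function(g, i, mode = c("isolate", "remove")) {
  mode <- match.arg(mode)
  a <- as.matrix(unclass(g))
  i <- as.integer(i)
  if (i < 1 || i > nrow(a))
    stop("node ", i, " is not in the graph")
  res <- set_centrality(a, list(name = as.character(i), indices = i),
                        mode = mode)
  res$lesion <- paste0("node ", i)
  res
}

#' Information centrality of a node set
#'
#' Efficiency loss caused by lesioning all nodes of a set at once:
#' `C_S = (Sigma(G) - Sigma(G')) / Sigma(G)` where `G'` has every edge
#' incident to any node of `S` deleted (`"isolate"`) or all of `S` removed
#' (`"remove"`, renormalized over the surviving nodes).
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @param s A `node_set`, or a plain integer vector of node indices.
#' @param mode `"isolate"` (default) or `"remove"`.
#' @return A `lesion_result`.
#' @export
set_centrality <- function(g, s, mode = c("isolate", "remove")) {
  mode <- match.arg(mode)
  a <- as.matrix(unclass(g))
  n <- nrow(a)
  if (is.numeric(s)) s <- list(name = paste(s, collapse = ","), indices = s)
  idx <- sort(unique(as.integer(s$indices)))
  if (length(idx) == 0) stop("empty node set")
  if (any(idx < 1) || any(idx > n)) stop("node set outside the graph")
  if (length(idx) == n)
    stop("cannot lesion every node of the graph")
  baseline <- efficiency_from_dist(shortest_paths(a))
  if (baseline == 0)
    stop("baseline efficiency is zero; centrality is undefined")
  if (mode == "isolate") {
    a2 <- a
    a2[idx, ] <- 0
    a2[, idx] <- 0
    lesioned <- efficiency_from_dist(shortest_paths(a2))
  } else {
    a2 <- a[-idx, -idx, drop = FALSE]
    if (nrow(a2) < 2)
      stop("fewer than 2 nodes survive the removal")
    lesioned <- efficiency_from_dist(shortest_paths(a2))
  }
  lesion_result(baseline, lesioned,
                lesion = paste0("set ", s$name), mode = mode)
}
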