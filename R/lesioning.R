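#' Systematic single-node lesion sweep
#'
#' Lesions every node in turn and records its efficiency loss (information
#' centrality), degree, and a min-max normalized loss in `[0, 1]`, together
#' with the summary statistics the sweep exists for: the mean efficiency of
#' the lesioned-network population, the mean loss, and the spread
#' (max - min) of losses across nodes.
#'
#' @param g A `group_adjacency` or binary adjacency matrix, `N >= 3`.
#' @param mode Lesion semantics, `"isolate"` (default) or `"remove"`; see
#'   [node_centrality()].
#' @param regions Optional `region_table` supplying node names.
#' @return A `sweep_result`: a data frame with columns `index`, `name`,
#'   `degree`, `loss`, `normalized_loss`, carrying attributes `baseline`
#'   (intact `Sigma(G)`), `mean_lesioned_efficiency`, `mean_loss`,
#'   `max_loss`, `min_loss`, `spread`, and `mode`.
#' @export
single_node_sweep <- function(g, mode = c("isolate", "remove"),
                              regions = NULL) {
  mode <- match.arg(mode)
  a <- as.matrix(unclass(g))
  n <- nrow(a)
  if (n < 3) stop("the sweep requires at least 3 nodes")
  baseline <- efficiency_from_dist(shortest_paths(a))
  if (baseline == 0)
    stop("baseline efficiency is zero; centrality is undefined")
  res <- lapply(seq_len(n), function(i) node_centrality(a, i, mode = mode))
  loss <- vapply(res, function(r) r$loss, numeric(1))
  lesioned <- vapply(res, function(r) r$lesioned, numeric(1))
  rng <- range(loss)
  norm <- if (rng[2] > rng[1]) (loss - rng[1]) / (rng[2] - rng[1]) else
    rep(0, n)
  nm <- if (!is.null(regions)) regions$name[seq_len(n)] else
    as.character(seq_len(n))
  out <- data.frame(index = seq_len(n), name = nm,
                    degree = as.integer(rowSums(a)),
                    loss = loss, normalized_loss = norm,
                    stringsAsFactors = FALSE)
  structure(out,
            baseline = baseline,
            mean_lesioned_efficiency = mean(lesioned),
            mean_loss = mean(loss),
            max_loss = rng[2], min_loss = rng[1], spread = diff(rng),
            mode = mode,
            class = c("sweep_result", "data.frame"))
}

#' Lesion a list of target networks
#'
#' Applies [set_centrality()] to each target set and tabulates the losses,
#' mirroring a structure / regions / efficiency-loss-percent report.
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @param targets List of `node_set` objects (e.g. from [target_network()]).
#' @param mode `"isolate"` (default) or `"remove"`.
#' @return A data frame with columns `structure`, `regions` (comma-joined
#'   indices), `n_regions`, `loss` (fraction), `loss_pct`.
#' @export
lesion_target_networks <- function(g, targets, mode = c("isolate", "remove")) {
  mode <- match.arg(mode)
  rows <- lapply(targets, function(s) {
    r <- set_centrality(g, s, mode = mode)
    data.frame(structure = s$name,
               regions = paste(s$indices, collapse = ", "),
               n_regions = length(s$indices),
               loss = r$loss,
               loss_pct = round(100 * r$loss, 2),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(structure = character(0), regions = character(0),
                      n_regions = integer(0), loss = numeric(0),
                      loss_pct = numeric(0)))
  do.call(rbind, rows)
}

#' Lesion the edges between two node sets
#'
#' Deletes every edge with one endpoint in `a` and the other in `b` (all
#' nodes are retained) and reports the efficiency loss of the edge-lesioned
#' graph.  With `a == b` this removes all edges internal to the set.
#' Removing absent edges is a no-op, so disconnected sets yield loss 0.
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @param a,b `node_set` objects or integer index vectors.
#' @return A `lesion_result` (mode `"edges"`); also carries the number of
#'   edges removed as `$n_removed`.
#' @export
lesion_edges_between <- function(g, a, b) {
  adj <- as.matrix(unclass(g))
  if (is.numeric(a)) a <- list(name = paste(a, collapse = ","), indices = a)
  if (is.numeric(b)) b <- list(name = paste(b, collapse = ","), indices = b)
  ia <- sort(unique(as.integer(a$indices)))
  ib <- sort(unique(as.integer(b$indices)))
  if (length(ia) == 0 || length(ib) == 0) stop("empty node set")
  n <- nrow(adj)
  if (any(c(ia, ib) < 1) || any(c(ia, ib) > n))
    stop("node set outside the graph")
  baseline <- efficiency_from_dist(shortest_paths(adj))
  if (baseline == 0)
    stop("baseline efficiency is zero; centrality is undefined")
  adj2 <- adj
  adj2[ia, ib] <- 0
  adj2[ib, ia] <- 0
  diag(adj2) <- 0
  lesioned <- efficiency_from_dist(shortest_paths(adj2))
  out <- lesion_result(baseline, lesioned,
                       lesion = paste0("edges ", a$name, " x ", b$name),
                       mode = "edges")
  out$n_removed <- (sum(adj) - sum(adj2)) / 2
  out
}

#' Hemispheric lesioning and asymmetry
#'
#' Lesions each hemisphere in turn and reports the two efficiency losses
#' and their absolute difference (the hemispheric-asymmetry contrast).  By
#' default the whole hemisphere node set is isolated (all its edges cut,
#' within- and cross-hemisphere alike); `method = "edges"` instead cuts
#' only the interhemispheric edges, leaving each hemisphere internally
#' intact.
#'
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @param table A `region_table` defining the hemisphere membership of each
#'   node (its first `N` rows are used).
#' @param mode `"isolate"` or `"remove"`, passed to [set_centrality()] when
#'   `method = "set"`.
#' @param method `"set"` (default: lesion the whole hemisphere node set) or
#'   `"edges"` (cut interhemispheric edges only).
#' @return A list with `left`, `right` (both `lesion_result`s) and
#'   `asymmetry = |left loss - right loss|`.
#' @export
lesion_hemisphere <- function(g, table = load_regions(),
                              mode = c("isolate", "remove"),
                              method = c("set", "edges")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  n <- nrow(as.matrix(unclass(g)))
  tab <- table[table$index <= n, , drop = FALSE]
  left <- node_set("left_hemisphere", tab$index[tab$hemisphere == "left"], tab)
  right <- node_set("right_hemisphere", tab$index[tab$hemisphere == "right"],
                    tab)
  if (method == "set") {
    rl <- set_centrality(g, left, mode = mode)
    rr <- set_centrality(g, right, mode = mode)
  } else {
    rl <- rr <- lesion_edges_between(g, left, right)
  }
  list(left = rl, right = rr, asymmetry = abs(rl$loss - rr$loss))
}

#' Ordinary least squares of normalized efficiency loss on degree
#'
#' Quantifies how well a node's connectivity degree predicts the efficiency
#' loss its lesioning causes.  Both the slope and the coefficient of
#' determination are returned, since either may be quoted as "the linear
#' regression" of such a scatter.
#'
#' @param sweep A `sweep_result` from [single_node_sweep()].
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
degree_loss_regression <- function(sweep) {
  if (nrow(sweep) < 3)
    stop("at least 3 nodes are required")
  if (length(unique(sweep$degree)) < 2)
    stop("degree is constant across nodes; the regression slope is undefined")
  fit <- stats::lm(normalized_loss ~ degree, data = sweep)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = nrow(sweep))
}
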