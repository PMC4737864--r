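#' Erdos-Renyi random adjacency
#'
#' Null fixture generator: each of the `n(n-1)/2` node pairs carries an edge
#' independently with probability `p`.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `group_adjacency` binary matrix.
#' @export
simulate_adjacency_er <- function(n, p, seed = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]")
  set.seed(seed)
  a <- matrix(0, n, n)
  upper <- upper.tri(a)
  a[upper] <- as.numeric(stats::runif(sum(upper)) < p)
  a <- a + t(a)
  group_adjacency(a, group = sprintf("er(n=%d, p=%g)", n, p))
}

#' Erdos-Renyi background with one planted hub
#'
#' Adds to an ER background a designated node wired to `hub_extra_degree`
#' uniformly chosen other nodes, giving a known ground-truth hub whose
#' recovery by the lesion sweep can be tested.
#'
#' @param n Number of nodes.
#' @param p_background Background edge probability.
#' @param hub_extra_degree Number of nodes the hub is wired to (at most
#'   `n - 1`).
#' @param seed Integer seed.
#' @return A list with `adjacency` (a `group_adjacency`) and `hub` (the
#'   planted hub's index).
#' @export
simulate_planted_hub <- function(n, p_background, hub_extra_degree, seed = 1) {
  n <- as.integer(n)
  hub_extra_degree <- as.integer(hub_extra_degree)
  if (hub_extra_degree > n - 1)
    stop("'hub_extra_degree' cannot exceed n - 1")
  g <- simulate_adjacency_er(n, p_background, seed = seed)
  hub <- sample.int(n, 1)
  targets <- sample(setdiff(seq_len(n), hub), hub_extra_degree)
  g[hub, targets] <- 1
  g[targets, hub] <- 1
  list(adjacency = group_adjacency(unclass(g),
                                   group = sprintf("planted_hub(n=%d)", n)),
       hub = hub)
}

#' Two-block (bihemispheric) random adjacency
#'
#' Fixture for hemisphere-lesioning tests: `2 * n_per_side` nodes split into
#' a left block (odd indices) and a right block (even indices), with
#' independent edges at density `p_within` inside a block and `p_between`
#' across blocks.  `p_within` may be a length-2 vector `(left, right)` for
#' asymmetric variants.
#'
#' @param n_per_side Nodes per hemisphere.
#' @param p_within Within-block edge probability (scalar, or `(left, right)`).
#' @param p_between Between-block edge probability.
#' @param seed Integer seed.
#' @return A `group_adjacency` on `2 * n_per_side` nodes.
#' @export
simulate_bihemispheric <- function(n_per_side, p_within, p_between, seed = 1) {
  n_per_side <- as.integer(n_per_side)
  stopifnot(n_per_side >= 1)
  p_within <- rep_len(p_within, 2)
  probs <- c(p_within, p_between)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("edge probabilities must lie in [0, 1]")
  set.seed(seed)
  n <- 2L * n_per_side
  side <- ifelse(seq_len(n) %% 2 == 1, 1L, 2L)  # 1 = left, 2 = right
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (side[i] == side[j]) p_within[side[i]] else p_between
      if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  group_adjacency(a, group = sprintf("bihemispheric(n=%d)", n))
}
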