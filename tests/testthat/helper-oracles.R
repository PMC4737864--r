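# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# All-pairs shortest paths by Floyd-Warshall on a binary adjacency.
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# Global efficiency by direct summation over ordered pairs.
oracle_efficiency <- function(a) {
  d <- fw_distances(a)
  n <- nrow(a)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (n * (n - 1))
}

# Loss from isolating a node set, via the oracle efficiency.
oracle_set_loss <- function(a, idx) {
  base <- oracle_efficiency(a)
  a2 <- a
  a2[idx, ] <- 0
  a2[, idx] <- 0
  (base - oracle_efficiency(a2)) / base
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# Random symmetric binary adjacency (plain matrix, no package code).
random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(stats::runif(sum(ut)) < p)
  a + t(a)
}

# Tiny 4-row region table used across atlas tests.
toy_regions <- function() {
  data.frame(index = 1:4, name = paste0("r", 1:4),
             hemisphere = c("left", "right", "left", "right"),
             stringsAsFactors = FALSE)
}

# Two K4 cliques joined (optionally) by one bridge edge between nodes 1, 5.
two_cliques <- function(bridge = FALSE) {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1
  a[5:8, 5:8] <- 1
  diag(a) <- 0
  if (bridge) a[1, 5] <- a[5, 1] <- 1
  a
}
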