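# Minimal exact big-integer arithmetic (nonnegative, addition only), enough
# for binomial coefficients via the Pascal recurrence well past the range of
# double precision.  A bignum is a numeric vector of base-1e9 limbs, little
# endian; limb sums stay below 2^31 so doubles hold them exactly.

.big_base <- 1e9

big_from_int <- function(x) {
  stopifnot(x >= 0, x < .big_base)
  as.numeric(x)
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .big_base) 1 else 0
    if (carry) s[i] <- s[i] - .big_base
  }
  if (carry) s <- c(s, 1)
  s
}

big_to_string <- function(a) {
  a <- rev(a)
  out <- paste0(as.character(a[1]),
                paste(sprintf("%09.0f", a[-1]), collapse = ""))
  out
}

# exact numeric if representable (< 2^53), else NA
big_to_number <- function(a) {
  v <- sum(a * .big_base^(seq_along(a) - 1))
  if (v < 2^53) v else NA_real_
}

#' Size of the single- and multi-node lesion population
#'
#' Counts, in exact integer arithmetic, the networks generated by
#' systematically deleting nodes from an `n`-node graph: both the
#' cumulative population `sum_{i=1..k} C(n, i)` of all deletions of up to
#' `k` nodes, and the single term `C(n, k)` (the networks with exactly `k`
#' nodes deleted).  Counts are exact for `n` well beyond 200, where
#' `C(n, k)` overflows double precision; values too large for exact
#' representation as a number are reported as `NA` alongside their exact
#' decimal string.
#'
#' @param n Number of nodes.
#' @param max_deleted Maximum number of deleted nodes `k`, `1 <= k <= n`.
#' @return A list with `cumulative` / `single_term` (numeric, exact or `NA`
#'   if above `2^53`) and `cumulative_exact` / `single_term_exact` (decimal
#'   strings).
#' @examples
#' count_lesion_networks(90, 1)$single_term    # 90
#' count_lesion_networks(90, 2)$single_term    # 4005
#' @export
count_lesion_networks <- function(n, max_deleted) {
  n <- as.integer(n)
  k <- as.integer(max_deleted)
  if (is.na(k) || k < 1 || k > n)
    stop("'max_deleted' must lie in 1..n")
  # Pascal recurrence: row[j] = C(i, j), kept only up to column k
  row <- list(big_from_int(1))  # C(0, 0)
  for (i in seq_len(n)) {
    upto <- min(i, k)
    new <- vector("list", upto + 1)
    new[[1]] <- big_from_int(1)
    for (j in seq_len(upto)) {
      left <- if (j <= length(row) - 1) row[[j + 1]] else big_from_int(0)
      new[[j + 1]] <- big_add(row[[j]], left)
    }
    row <- new
  }
  cum <- big_from_int(0)
  for (j in seq_len(k) + 1) cum <- big_add(cum, row[[j]])
  single <- row[[k + 1]]
  list(cumulative = big_to_number(cum),
       single_term = big_to_number(single),
       cumulative_exact = big_to_string(cum),
       single_term_exact = big_to_string(single))
}
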