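#' Group adjacency matrix
#'
#' Light wrapper marking a validated binary, symmetric, zero-diagonal
#' adjacency matrix, with provenance (significance level, number of tests,
#' group label) carried as attributes.
#'
#' @param values An `N x N` 0/1 matrix.
#' @param alpha Familywise significance level used to build the graph, if
#'   any.
#' @param group Group label.
#' @param m Number of pairwise tests behind the graph, if any.
#' @return The matrix with class `group_adjacency` and attributes `alpha`,
#'   `group`, `m`.
#' @export
group_adjacency <- function(values, alpha = NA_real_, group = NA_character_,
                            m = NA_integer_) {
  values <- as.matrix(unclass(values))
  validate_adjacency(values)
  dimnames(values) <- list(seq_len(nrow(values)), seq_len(nrow(values)))
  structure(values, class = c("group_adjacency", "matrix", "array"),
            alpha = alpha, group = group, m = m)
}

validate_adjacency <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  bad <- which(!(a %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(a))
    stop("adjacency must be binary; first offending cell [", rc[1], ", ",
         rc[2], "] = ", a[bad[1]])
  }
  asym <- which(a != t(a))
  if (length(asym) > 0) {
    rc <- arrayInd(asym[1], dim(a))
    stop("adjacency must be symmetric; first offending cell [", rc[1], ", ",
         rc[2], "]")
  }
  if (any(diag(a) != 0))
    stop("adjacency must have a zero diagonal (self-loop at node ",
         which(diag(a) != 0)[1], ")")
  invisible(a)
}

#' @export
print.group_adjacency <- function(x, ...) {
  s <- graph_summary(x)
  cat("<group_adjacency> ", nrow(x), " nodes, ", s$n_edges, " edges",
      if (!is.na(attr(x, "group"))) paste0(" [", attr(x, "group"), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Pearson correlation matrix of one subject's regional time series
#'
#' @param ts A `subject_ts` (list with a `T x N` `data` matrix) or a plain
#'   `T x N` numeric matrix.
#' @return An `N x N` symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ts) {
  x <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (nrow(x) < 3)
    stop("at least 3 timepoints are required")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  r <- stats::cor(x)
  dimnames(r) <- list(seq_len(ncol(x)), seq_len(ncol(x)))
  r
}

#' Fisher r-to-z transform
#'
#' Applies `z = atanh(r)` elementwise to the off-diagonal entries of a
#' correlation matrix.  Correlations within `1e-7` of +/-1 are clamped
#' before the transform so that degenerate (perfectly correlated) inputs do
#' not inject infinities into the downstream t-tests.  The diagonal is set
#' to zero (it carries no information and is never tested).
#'
#' @param r A symmetric correlation matrix with entries in `[-1, 1]`.
#' @return The matrix of z-values.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  clamp <- 1 - 1e-7
  r <- pmin(pmax(r, -clamp), clamp)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Edgewise one-sample t-tests across subjects
#'
#' For every region pair `(i, j)`, tests whether the subjects'
#' Fisher-transformed correlations differ from zero: a one-sample t with
#' `df = n_subjects - 1` and a two-tailed p-value.  A pair with zero
#' across-subject variance is resolved by the limit of the t statistic:
#' `p = 1` when the mean z is exactly zero, `p = 0` otherwise.
#'
#' @param z_list List of `N x N` z-matrices, one per subject (at least 2).
#' @return A `pvalue_matrix`: list with `p` (symmetric `N x N` matrix of
#'   two-tailed p-values, diagonal `NA`), `t` (t statistics), `mean_z`, and
#'   `df`.
#' @export
edgewise_ttest <- function(z_list) {
  if (length(z_list) < 2)
    stop("at least 2 subjects are required for the edgewise t-test")
  dims <- vapply(z_list, function(z) nrow(as.matrix(z)), integer(1))
  if (length(unique(dims)) != 1)
    stop("subjects have differing numbers of regions")
  n <- length(z_list)
  nr <- dims[1]
  arr <- array(unlist(lapply(z_list, as.matrix)), dim = c(nr, nr, n))
  mz <- apply(arr, c(1, 2), mean)
  sz <- apply(arr, c(1, 2), stats::sd)
  tval <- mz / (sz / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  degen <- sz == 0
  p[degen & mz == 0] <- 1
  p[degen & mz != 0] <- 0
  tval[degen] <- ifelse(mz[degen] == 0, 0, sign(mz[degen]) * Inf)
  diag(p) <- NA_real_
  diag(tval) <- NA_real_
  structure(list(p = p, t = tval, mean_z = mz, df = n - 1L,
                 n_subjects = n),
            class = "pvalue_matrix")
}

#' Holm step-down thresholding into a binary graph
#'
#' Applies the Bonferroni-Holm procedure to the `m = N(N-1)/2` pairwise
#' p-values: sort ascending and reject the k-th smallest while
#' `p_(k) <= alpha / (m - k + 1)`, stopping at the first failure.  A pair
#' becomes an edge iff its test is rejected (and, under
#' `edge_sign = "positive"`, its mean z is positive; `m` is unaffected by
#' the sign policy).
#'
#' @param p A `pvalue_matrix` from [edgewise_ttest()], or a symmetric matrix
#'   of p-values.
#' @param alpha Familywise error level in `(0, 1)`.
#' @param edge_sign `"both"` (default): significant positive and negative
#'   mean correlations both become edges; `"positive"`: only positive ones.
#' @param group Group label recorded on the output.
#' @return A [group_adjacency()] with attributes `alpha` and `m`.
#' @export
holm_adjacency <- function(p, alpha = 0.05, edge_sign = c("both", "positive"),
                           group = NA_character_) {
  edge_sign <- match.arg(edge_sign)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  mean_z <- NULL
  if (inherits(p, "pvalue_matrix")) {
    mean_z <- p$mean_z
    p <- p$p
  }
  p <- as.matrix(p)
  nr <- nrow(p)
  ut <- which(upper.tri(p))
  pv <- p[ut]
  m <- length(pv)   # fixed at N(N-1)/2 regardless of degenerate pairs
  ord <- order(pv)  # stable; ties share a decision boundary
  thresh <- alpha / (m - seq_len(m) + 1)
  ok <- pv[ord] <= thresh
  first_fail <- which(!ok)[1]
  rejected <- logical(m)
  if (is.na(first_fail)) {
    rejected[] <- TRUE
  } else if (first_fail > 1) {
    rejected[ord[seq_len(first_fail - 1)]] <- TRUE
  }
  if (edge_sign == "positive") {
    if (is.null(mean_z))
      stop("edge_sign = 'positive' requires a pvalue_matrix input (mean z ",
           "values are needed to orient the edges)")
    rejected <- rejected & (mean_z[ut] > 0)
  }
  a <- matrix(0, nr, nr)
  a[ut] <- as.numeric(rejected)
  a <- a + t(a)
  group_adjacency(a, alpha = alpha, group = group, m = m)
}

#' Summary statistics of a binary graph
#'
#' @param g A `group_adjacency` or plain binary adjacency matrix.
#' @return A list with `n_nodes`, `n_edges`, `degree` (integer vector),
#'   `mean_degree` (`2 * n_edges / N`), and `n_isolated`.
#' @export
graph_summary <- function(g) {
  a <- as.matrix(unclass(g))
  validate_adjacency(a)
  deg <- as.integer(rowSums(a))
  list(n_nodes = nrow(a),
       n_edges = sum(a) / 2,
       degree = deg,
       mean_degree = sum(a) / nrow(a),
       n_isolated = sum(deg == 0))
}

#' Build a group graph from subject time series in one call
#'
#' Convenience wrapper chaining [pearson_matrix()], [fisher_z()],
#' [edgewise_ttest()] and [holm_adjacency()].
#'
#' @param ts_list List of `subject_ts` objects (or `T x N` matrices).
#' @inheritParams holm_adjacency
#' @return A [group_adjacency()].
#' @export
build_group_graph <- function(ts_list, alpha = 0.05,
                              edge_sign = c("both", "positive"),
                              group = NA_character_) {
  z <- lapply(ts_list, function(ts) fisher_z(pearson_matrix(ts)))
  holm_adjacency(edgewise_ttest(z), alpha = alpha,
                 edge_sign = match.arg(edge_sign), group = group)
}
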