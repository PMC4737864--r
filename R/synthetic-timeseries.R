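#' Ground truth for the synthetic signal model
#'
#' Describes the latent structure from which regional time series are drawn:
#' a partition of regions into communities, within- and between-community
#' correlation levels, an optional set of hub regions that load on every
#' community factor, and an optional first-order autoregressive smoothing
#' coefficient that mimics band-limited (0.01--0.08 Hz-like) signals.
#'
#' The signal model for region `i` of community `c(i)` at time `t` is
#' `x_i(t) = sqrt(rho_w) * f_c(t) + sqrt(1 - rho_w) * eps_i(t)`, with
#' standard-normal community factors `f_c` and independent noise `eps_i`.
#' Between-community correlation `rho_b` is induced by a shared global
#' factor: `f_c = a_c * g + sqrt(1 - a_c^2) * h_c` with
#' `a_c^2 = rho_b / rho_w_c`, so the expected Pearson correlation is
#' `rho_w_c` within community `c` and `rho_b` between communities.  Hub
#' regions additionally load on all other community factors with loading
#' `hub_loading`.
#'
#' @param n_regions Number of regions (columns of the generated series).
#' @param n_communities Number of communities `K`; regions are assigned to
#'   contiguous, near-equal blocks unless `module_assignment` is given.
#' @param rho_within Within-community correlation, a scalar in `[0, 1)` or a
#'   vector of length `K` (heterogeneous communities).
#' @param rho_between Between-community correlation in `[0, 1)`; must be
#'   strictly below every `rho_within` unless zero.
#' @param hub_indices Region indices that load on every community factor.
#' @param hub_loading Loading `lambda` of hubs on non-home community factors.
#' @param ar_phi First-order autoregressive coefficient in `[0, 1)`; `0`
#'   (the default) disables temporal smoothing.
#' @param module_assignment Optional integer vector mapping each region to a
#'   community id in `1..K`.
#' @return A `simulation_truth` object (list).
#' @export
simulation_truth <- function(n_regions, n_communities,
                             rho_within, rho_between = 0,
                             hub_indices = integer(0), hub_loading = 0.3,
                             ar_phi = 0, module_assignment = NULL) {
  n_regions <- as.integer(n_regions)
  n_communities <- as.integer(n_communities)
  stopifnot(n_regions >= 1, n_communities >= 1, n_communities <= n_regions)
  if (length(rho_within) == 1)
    rho_within <- rep(rho_within, n_communities)
  if (length(rho_within) != n_communities)
    stop("'rho_within' must have length 1 or n_communities")
  if (any(rho_within < 0) || any(rho_within >= 1) ||
      rho_between < 0 || rho_between >= 1)
    stop("correlation parameters must lie in [0, 1)")
  if (rho_between > 0 && any(rho_within <= rho_between))
    stop("'rho_between' must be strictly smaller than every 'rho_within'")
  if (ar_phi < 0 || ar_phi >= 1)
    stop("'ar_phi' must lie in [0, 1)")
  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_communities), n_regions))
  }
  module_assignment <- as.integer(module_assignment)
  if (length(module_assignment) != n_regions ||
      !all(module_assignment %in% seq_len(n_communities)))
    stop("'module_assignment' must map every region to a community in 1..K")
  hub_indices <- sort(unique(as.integer(hub_indices)))
  if (length(hub_indices) > 0 &&
      (min(hub_indices) < 1 || max(hub_indices) > n_regions))
    stop("'hub_indices' out of range")
  structure(list(
    n_regions = n_regions,
    n_communities = n_communities,
    module_assignment = module_assignment,
    rho_within = rho_within,
    rho_between = rho_between,
    hub_indices = hub_indices,
    hub_loading = hub_loading,
    ar_phi = ar_phi
  ), class = "simulation_truth")
}

#' Group presets for the synthetic generator
#'
#' Two qualitative regimes mirroring the young/old contrast the analysis is
#' designed around: `"young-like"` has six equally coherent communities
#' (`rho_within = 0.5`) plus four hub regions that correlate with every
#' community, producing a dense, fairly homogeneous graph after
#' thresholding; `"old-like"` has the same six communities with
#' heterogeneous coherence (mean 0.5 halved to mean 0.3, spanning 0.08 to
#' 0.50) and no hubs, so the weakest communities sit in the partial-detection
#' regime and the thresholded graph comes out sparse and irregular.
#'
#' @param name `"young-like"` or `"old-like"`.
#' @param n_regions Number of regions (default 90).
#' @return A [simulation_truth()] object.
#' @export
group_preset <- function(name = c("young-like", "old-like"), n_regions = 90) {
  name <- match.arg(name)
  k <- 6L
  block <- ceiling(n_regions / k)
  if (name == "young-like") {
    # one hub in each of the first four communities
    hubs <- 1L + block * 0:3
    simulation_truth(n_regions, k, rho_within = 0.5, rho_between = 0.05,
                     hub_indices = hubs, hub_loading = 0.3)
  } else {
    simulation_truth(n_regions, k,
                     rho_within = c(0.08, 0.14, 0.22, 0.34, 0.46, 0.56),
                     rho_between = 0.02)
  }
}

#' Simulate multi-subject regional time series
#'
#' Draws `n_subjects` independent realizations of the latent-factor signal
#' model described in [simulation_truth()].  Output is deterministic given
#' `seed` (the function seeds R's RNG).
#'
#' @param n_subjects Number of subjects.
#' @param n_timepoints Number of timepoints `T` per subject (at least 3).
#' @param truth A [simulation_truth()] object.
#' @param group Group label attached to every subject (`"young"`/`"old"`).
#' @param seed Integer seed.
#' @return A list of `subject_ts` objects, each a list with `subject_id`,
#'   `group`, and `data` (a `T x N` numeric matrix, columns named by region
#'   index).
#' @examples
#' truth <- simulation_truth(n_regions = 10, n_communities = 2,
#'                           rho_within = 0.5)
#' ts <- simulate_group_timeseries(3, 100, truth, seed = 1)
#' dim(ts[[1]]$data)  # 100 x 10
#' @export
simulate_group_timeseries <- function(n_subjects, n_timepoints, truth,
                                      group = "young", seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  if (n_subjects < 1) stop("'n_subjects' must be positive")
  if (n_timepoints < 3) stop("'n_timepoints' must be at least 3")
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    structure(list(
      subject_id = sprintf("%s_%02d", group, s),
      group = group,
      data = simulate_subject_matrix(n_timepoints, truth)
    ), class = "subject_ts")
  })
}

# One T x N draw from the latent-factor model; uses the current RNG state.
simulate_subject_matrix <- function(n_timepoints, truth) {
  n <- truth$n_regions
  k <- truth$n_communities
  g <- stats::rnorm(n_timepoints)
  h <- matrix(stats::rnorm(n_timepoints * k), n_timepoints, k)
  # community factors, correlated through the global factor g
  a <- ifelse(truth$rho_within > 0,
              sqrt(truth$rho_between / truth$rho_within), 0)
  f <- sweep(h, 2, sqrt(1 - a^2), "*") + outer(g, a)
  eps <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  cc <- truth$module_assignment
  rho <- truth$rho_within[cc]
  x <- f[, cc, drop = FALSE] %*% diag(sqrt(rho), n) +
    eps %*% diag(sqrt(1 - rho), n)
  for (i in truth$hub_indices) {
    others <- setdiff(seq_len(k), cc[i])
    x[, i] <- x[, i] +
      truth$hub_loading * rowSums(f[, others, drop = FALSE])
  }
  if (truth$ar_phi > 0) {
    # same recursive filter on every column preserves the expected
    # contemporaneous correlation structure
    x <- apply(x, 2, function(col)
      as.numeric(stats::filter(col, truth$ar_phi, method = "recursive")))
  }
  colnames(x) <- seq_len(n)
  x
}
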