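---
title: "Methods: building and lesioning resting-state connectivity graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and lesioning resting-state connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlesion)
```

## The analysis in one paragraph

Resting-state fMRI yields, per subject, one mean time series per
parcellated brain region (here: the 90-region AAL atlas, cortical and
subcortical, odd indices left hemisphere, even indices right).  The
package condenses a group of subjects into a single undirected binary
graph — nodes are regions, edges are interregional correlations that are
significant at the group level — and then probes that graph's robustness
by *lesioning*: deleting the edges of single nodes, of whole target
networks such as the default mode network (DMN), of specific edge sets, or
of entire hemispheres, and measuring how much communication efficiency
each deletion costs.

## Graph construction

For each subject the `T x N` regional time-series matrix gives an `N x N`
Pearson correlation matrix (`pearson_matrix()`).  Correlations are
variance-stabilized with Fisher's r-to-z, `z = atanh(r)` (`fisher_z()`).
For each of the `m = N(N-1)/2` region pairs (4005 for `N = 90`), a
two-tailed one-sample t-test across subjects asks whether the mean z
differs from zero (`edgewise_ttest()`, `df = n_subjects - 1`).  The
Bonferroni–Holm step-down procedure (`holm_adjacency()`) controls the
familywise error rate over all `m` tests: p-values are sorted ascending
and the k-th smallest is rejected while `p_(k) <= alpha / (m - k + 1)`,
stopping at the first failure.  Rejected pairs become edges.

Numerical choices in this stage:

* **Clamping at |r| = 1.** `atanh` diverges at ±1, and a single infinite z
  poisons the t-test of its pair.  Correlations within `1e-7` of ±1 are
  clamped before the transform.  Perfect correlations arise only in
  degenerate (e.g. duplicated-column) inputs, where the clamped z ≈ 8.4
  still dominates any realistic value.
* **Zero-variance pairs.** If all subjects have identical z at a pair, the
  t statistic is `0/0`.  We resolve it by its limit: `p = 1` when the mean
  is exactly zero, `p = 0` otherwise.
* **`m` is fixed at `N(N-1)/2`** even if some pairs are degenerate, so the
  correction level never silently changes with the data.
* **Ties** among sorted p-values are kept in stable order and share the
  same decision boundary, the standard step-down convention.
* **Edge sign.** The t-test is two-tailed, and by default both significant
  positive and significant negative mean correlations become edges
  (`edge_sign = "both"`); `edge_sign = "positive"` restricts edges to
  positive mean z without changing `m`.  Anticorrelations in global-signal
  -regressed data are interpretable, so neither choice is forced.
* **`alpha` defaults to 0.05**; it is a parameter of `holm_adjacency()`
  and `run_pipeline()` and is recorded on the output graph.

## Efficiency and information centrality

The efficiency of communication between nodes `i` and `j` is the inverse
geodesic distance, `eps_ij = 1/d_ij`, and exactly zero for unreachable
pairs.  Global efficiency is the average over all `N(N-1)` ordered pairs:

```
Sigma(G) = (1 / (N(N-1))) * sum_{i != j} 1 / d_ij
```

`Sigma` is 1 for the complete graph and 0 for the edgeless one.
Distances come from breadth-first search on the unweighted graph (via
igraph); unreachable pairs are represented by an `Inf` sentinel, never by
a large finite number, so their efficiency contribution is exactly zero
rather than merely small.

The *information centrality* (efficiency loss) of a node or node set is
the relative drop in `Sigma` when it is lesioned:

```
C_S = (Sigma(G) - Sigma(G')) / Sigma(G)
```

Two lesioning semantics are offered, because "removing a node" is
genuinely ambiguous:

* **`isolate` (default):** delete every edge incident to the set, keep all
  `N` nodes.  This is the information-centrality convention of Latora and
  Marchiori; `Sigma` can only decrease, so `C` lies in `[0, 1]`, and
  supersets always lose at least as much (`S ⊆ S'` implies
  `C_S <= C_S'`).
* **`remove`:** delete the nodes and renormalize `Sigma` over the
  surviving `(N-1)(N-2)` ordered pairs.  This is provided for sensitivity
  analysis.  Note that it is *not* sign-definite: removing a node that is
  already disconnected shrinks the denominator while the efficiency sum is
  unchanged, giving `C = -2/(N-2)` rather than 0.  Every report states
  which mode produced it.

A baseline of `Sigma = 0` (edgeless graph) makes `C` undefined; all
centrality functions flag this as an error rather than returning `NaN`.

## The lesion experiments

* **`single_node_sweep()`** lesions each node in turn, recording degree,
  loss, and a min–max normalized loss in `[0, 1]` (`(C_i - min C) /
  (max C - min C)`; all zeros when losses are constant).  The sweep's
  summary — mean lesioned efficiency, mean loss, and the spread
  `max - min` — is the robustness signature of the graph: homogeneous
  small losses mean resilience to single lesions, a wide spread means a
  few critical nodes.
* **`count_lesion_networks()`** gives the size of the lesion population:
  both the cumulative count `sum_{i=1..k} C(N, i)` of all deletions of up
  to `k` nodes and the single term `C(N, k)` (the two are easily
  conflated: for `N = 90`, `k = 2`, the single term is 4005 while the
  cumulative count is 4095, so both are returned).  Binomials are computed
  by the Pascal recurrence in exact base-1e9 integer arithmetic, valid far
  beyond the `2^53` limit of doubles (checked at `n = 200`); values too
  large for an exact double are reported as `NA` beside their exact
  decimal string.
* **`lesion_target_networks()`** applies set centrality to configured
  region sets.  The sets live in a YAML file
  (`inst/extdata/target_networks.yaml`), not in code, so users can
  redefine them.  The default `"DMN"` is the anatomically standard
  definition — medial prefrontal (23–26), posterior cingulate/precuneus
  (35, 36, 67, 68), bilateral inferior parietal (61, 62) — while
  `"DMN_table1"` preserves a published variant of that list; the two
  disagree and we default to the anatomically standard one.  One shipped
  set, `insula_cingulate_table1`, reproduces a published row that prints
  the same indices as the DMN row; this is almost certainly a typesetting
  error in its source, so the set is shipped verbatim with a warning
  rather than silently "corrected".
* **`lesion_edges_between()`** deletes only the edges joining two sets
  (all nodes survive).  With `a == b` it removes the set's internal edges.
  Removing absent edges is a no-op with loss 0 — disconnected structures
  cost nothing to disconnect.  The pipeline's standard rows are within-DMN
  edges, left–right hippocampal/parahippocampal edges (`{37,39}` vs
  `{38,40}`), hippocampus–DMN edges, and frontal–striatum edges; the
  striatum defaults to caudate + putamen (`{71..74}`), with pallidum
  excluded but addable in the config, since "striatum" has no single
  accepted AAL definition.
* **`lesion_hemisphere()`** lesions each hemisphere and reports both
  losses and their absolute difference, the hemispheric-asymmetry
  contrast.  The default semantics isolate the full hemisphere node set
  (cutting its internal edges too), which matches the large (>70%) losses
  such lesions produce on realistic graphs; `method = "edges"` cuts only
  interhemispheric edges for the milder "split-brain" variant.  The
  odd/even hemisphere convention is the standard AAL interleaving and is
  overridable through the region-metadata file.
* **`degree_loss_regression()`** fits normalized loss on degree by
  ordinary least squares and returns slope, intercept, *and* R², because a
  bare "regression = 0.755" quoted for such a scatter is ambiguous between
  the two.

## The synthetic generator

No imaging data ship with the package; `simulate_group_timeseries()`
provides test data whose ground truth is known.  Region `i` of community
`c(i)` follows a latent-factor block model:

```
x_i(t) = sqrt(rho_w) * f_c(i)(t) + sqrt(1 - rho_w) * eps_i(t)
```

with standard-normal community factors and independent noise, so the
expected within-community Pearson correlation is exactly `rho_w`.
Between-community correlation `rho_b` enters through a global factor
shared by all community factors (`f_c = a_c g + sqrt(1 - a_c^2) h_c`,
`a_c^2 = rho_b / rho_w,c`), which requires `rho_b < rho_w`.  Hub regions
additionally load on every other community's factor with loading
`lambda`, making them the correlational bridges of the system.  An
optional AR(1) recursion (`ar_phi`) smooths all series with the same
filter, mimicking band-limited signals without changing expected
contemporaneous correlations; it is off by default because the group
t-test treats subjects, not timepoints, as replicates.

Two presets encode the study conditions the package is exercised under,
with 20 subjects and 150 timepoints per group as the default problem
size:

* **`young-like`** — six communities, uniform `rho_w = 0.5`,
  `rho_b = 0.05`, four hubs with `lambda = 0.3`.  At `n = 20` subjects and
  `T = 150` the within-community t statistics (≈30) and the hub-edge
  statistics (≈9) sit far above the Holm threshold (|t| ≈ 6.5 at
  `alpha = 0.05`, `m = 4005`), so the graph comes out dense and
  homogeneous.
* **`old-like`** — the same six communities with heterogeneous coherence
  `rho_w = (0.08, 0.14, 0.22, 0.34, 0.46, 0.56)` (mean 0.3), no hubs,
  `rho_b = 0.02`.  The weakest communities produce t statistics near the
  threshold, so their edges are detected only partially and the graph
  comes out sparse and irregular, with isolated nodes and occasional
  cut vertices — the regime in which single-node lesions have wildly
  unequal costs.

These values were fixed once, from the power analysis above, as a
caricature of the dense-young / sparse-old contrast; no attempt is made
to match any particular empirical edge count.

What the generator does *not* emulate: hemodynamics, scanner noise and
motion artifacts, spatial autocorrelation between neighboring parcels,
heavy-tailed or nonstationary signals, and subject-level heterogeneity of
the community structure itself.  Tests passing on this model therefore
certify the pipeline's statistics and graph analytics, not the
physiological validity of any particular dataset.

Graph-level generators (`simulate_adjacency_er()`,
`simulate_planted_hub()`, `simulate_bihemispheric()`) bypass the
time-series stage for metric-level tests: a null model, a known hub whose
recovery by the sweep can be scored, and a two-block graph with
controllable hemispheric asymmetry.  All generators are deterministic
given their seed.

## Verification strategy and problem sizes

The test suite checks every metric against an independent brute-force
oracle (Floyd–Warshall distances plus direct summation) to `1e-12` on 500
random graphs of up to 30 nodes and on closed-form fixtures (paths,
stars, cliques); monotonicity and nonnegativity of efficiency loss over
200 random graph/set draws; familywise error control of the thresholding
on 500 independent-noise simulations (20 regions, 20 subjects, 150
timepoints); and recovery of planted structure (hub identification over
200 seeds; the dense-vs-sparse and narrow-vs-wide-spread preset contrast
over 50 paired seeds at the full 90-region size).  These sizes keep the
whole suite in the minutes range while leaving Monte-Carlo margins wide;
they are stated here so that reruns at larger sizes are a one-line
change.

## Known limitations

* Binary, undirected graphs only; no weighted or directed efficiency.
* One graph per group, not per subject — between-group inference on the
  derived metrics (beyond the qualitative contrasts) is out of scope.
* Heterogeneous degrees of freedom (missing data per pair) are not
  supported; every subject must contribute every region.
* The min–max normalization of sweep losses is scale-free but makes
  normalized values incomparable across graphs; compare raw losses when
  contrasting groups.
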