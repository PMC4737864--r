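# netlesion

Robustness analysis of resting-state functional-connectivity brain
networks by simulated lesioning.

Resting-state fMRI studies of aging repeatedly find that older adults
show weaker functional connectivity than young adults, but *which*
regions and subnetworks carry the communication load — and how brittle
the network is to their loss — requires a graph-level analysis.
`netlesion` implements that analysis end to end for researchers working
with parcellated regional time series (the 90-region AAL atlas by
default): it builds one binary graph per group and quantifies the cost of
knocking out nodes, networks, edge sets, or hemispheres.

## The method

**Graph construction.** For each subject, Pearson correlations between
all pairs of regional time series; Fisher's `z = atanh(r)` to stabilize
variance; for each of the `m = N(N−1)/2` pairs (4005 for `N = 90`) a
two-tailed one-sample t-test of the subjects' z-values against zero; a
Bonferroni–Holm step-down correction at level `α` turns the significant
pairs into the edges of an undirected binary graph.

**Efficiency.** Pair efficiency is the inverse geodesic distance
`ε_ij = 1/d_ij` (0 for unreachable pairs), and global efficiency is its
average over ordered pairs,

    Σ(G) = (1 / (N(N−1))) · Σ_{i≠j} 1/d_ij ,

which is 1 for the complete graph and 0 for the edgeless one.

**Lesioning.** The information centrality (efficiency loss) of a node or
node set S is the relative efficiency drop after its lesioning,

    C_S = (Σ(G) − Σ(G′)) / Σ(G) ,

where G′ has all edges incident to S removed (default `isolate` mode; a
`remove` mode that deletes the nodes and renormalizes is also provided).
On top of this the package implements the systematic single-node sweep
(with degree-vs-loss regression and exact lesion-population counts),
target-network lesioning (DMN, lobes, limbic and central structures —
all configurable), edge-set lesioning (e.g. hippocampus–DMN edges), and
hemispheric lesioning with an asymmetry contrast.

A synthetic generator (`simulate_group_timeseries()` with `"young-like"`
and `"old-like"` presets) produces modular, band-limited-like regional
signals with planted community and hub structure, so the entire pipeline
runs and is testable without any imaging data.

## Worked example

```r
library(netlesion)

# simulate a 20-subject group of 90-region time series and build its graph
truth <- group_preset("young-like")
ts    <- simulate_group_timeseries(20, 150, truth, group = "young", seed = 7)
g     <- build_group_graph(ts, alpha = 0.05)
g
#> <group_adjacency> 90 nodes, 989 edges

global_efficiency(g)
#> [1] 0.6234707

# lesion the default mode network
dmn <- target_network("DMN")
set_centrality(g, dmn)
#> <lesion_result> set DMN [isolate]: Sigma 0.6235 -> 0.4960, loss 20.44%

# systematic single-node sweep
sw <- single_node_sweep(g)
c(mean_loss = attr(sw, "mean_loss"), spread = attr(sw, "spread"))
#>  mean_loss     spread
#> 0.02222222 0.01441730

# hemispheric lesioning
h <- lesion_hemisphere(g)
round(100 * c(left = h$left$loss, right = h$right$loss, asym = h$asymmetry), 2)
#>  left right  asym
#> 75.41 75.55  0.14

# exact lesion-population combinatorics
unlist(count_lesion_networks(90, 2)[c("single_term", "cumulative")])
#> single_term  cumulative
#>        4005        4095
```

Reading the output: the thresholded group graph keeps 989 of the 4005
tested pairs as edges and transmits information at 62% of the efficiency
of a complete graph.  Isolating the 10-region DMN costs 20.4% of that
efficiency; the average single-node lesion costs 2.2%, with only a 1.4
percentage-point spread between the most and least critical node —
single lesions are well tolerated by this dense synthetic group.
Silencing a whole hemisphere costs about 75% either way, and the two
hemispheres are nearly interchangeable (asymmetry 0.14 points).  Exactly
4005 two-node deletions are possible (4095 counting one-node deletions
too).

`run_pipeline()` drives all of the above from a single config (synthetic
presets or time-series manifests on disk) and writes adjacencies, sweep
tables, lesion tables, and summary JSON per group.  A thin command-line
wrapper with `run`, `simulate`, `sweep`, and `count` subcommands is
installed at `inst/scripts/netlesion`.

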