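---
title: "Prioritizing drug targets by network maximum flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing drug targets by network maximum flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetflow)
```

## The problem and the model

Given a disease with a curated set of disease genes $D$ and a set of
candidate proteins $C$ (typically targets of approved drugs), we want to
rank the candidates by how strongly a perturbation at each one could
influence the disease genes through the cell's interaction network. The
premise is that a good target need not be differentially expressed itself,
nor a topological hub; what matters is the aggregate capacity of all routes
— not only shortest paths — from the candidate to the disease genes.

`targetflow` formalizes this as a maximum-flow problem on a partially
directed interactome:

* **Topology.** Protein–protein interactions are bidirectional and are
  expanded into two antiparallel arcs; transcription-factor → gene
  regulation is a single directed arc. Arcs are independent: each direction
  of a PPI carries its own capacity rather than sharing a budget, which is
  the standard reduction of undirected edges for flow algorithms.
* **Capacities.** Every arc between genes $i$ and $j$ gets
  $w_{ij} = |R_{ij}| \,\bigl(|E_{ci}-E_{ni}| + |E_{cj}-E_{nj}|\bigr)$,
  where $R_{ij}$ is the Pearson correlation of the two genes across cancer
  samples and $E_{c\cdot}, E_{n\cdot}$ are the per-gene mean log2
  expressions in cancer and normal samples. Correlation is computed on
  cancer samples only because the network of interest is the one operating
  in the disease state; the absolute value keeps inhibitory
  (anti-correlated) coupling as usable capacity. Uncorrelated or
  non-differential pairs get capacity 0 and can carry no flow.
* **Per-candidate flow problem.** A dummy source $S$ is wired to the
  candidate and a dummy sink $T$ receives an arc from every disease gene,
  all at an effectively infinite capacity, realized as
  `big_m` = (sum of all finite capacities) + 1 — any value strictly above
  the total finite capacity is equivalent, and keeping it finite keeps the
  arithmetic exact. A disease gene that is itself a candidate is linked
  only on the source side: giving it a sink arc would hand it unbounded
  flow for free. The candidate's score $F(D_u)$ is the maximum $S$–$T$
  flow.

## The solver

The maximum flow is computed by push-relabel. Heights are initialized to
each node's BFS shortest-arc-count distance to $T$ (the sink at 0, the
source pinned at $|V|$), nodes that cannot reach the sink get the sentinel
height $|V|$ so no effort is wasted pushing toward dead ends. Active nodes
are discharged highest-label first with FIFO order among equal labels;
relabeling lifts a node to one above its lowest residual neighbour. We
deliberately run the textbook algorithm without periodic global
relabeling: at the network sizes the package targets (hundreds to a few
thousand nodes) the plain algorithm is already fast, and fewer moving
parts are easier to verify — the flow value is identical either way.

Two properties matter for interpretation:

* The flow **value** is unique (max-flow/min-cut), and the package
  cross-checks its solver against an independent shortest-augmenting-path
  implementation (`edmonds_karp_oracle()`) and exhaustive cut enumeration
  in its test suite.
* The **per-arc decomposition is not unique**. All iteration orders in the
  solver are fixed (lexicographic gene ids), so results are bit-identical
  across runs of this package, but a different optimal solver could route
  the same value differently, which affects the affected-genes score
  below. Flow circulating both ways along a PPI arc pair is cancelled
  before reporting, so reported arc flows are net flows.

Numerical notes: capacities are doubles; residuals below $10^{-12}$ are
treated as zero. Zero-capacity arcs stay in the topology (they count
toward in-degrees) but are never admissible.

## The affected-genes score

Inhibiting a protein perturbs everything its influence reaches, so a
candidate whose flow fans out widely is more likely to produce off-target
effects. For each non-dummy node $i$ with positive inflow,
$P_i = F_i / K_i$, where $K_i$ is the node's in-degree in the augmented
network and $F_i$ the number of its incoming arcs carrying positive flow;
the candidate's total is $AG = \sum_i P_i$. The dummy arcs participate:
the $S$→candidate arc counts in both $F$ and $K$ of the candidate, while
$S$ and $T$ themselves are excluded from the sum — on the bundled
seven-gene example this reading reproduces the reference values exactly
($P = 0.5$ at each of the four flow-receiving nodes, $AG = 2$). Disease
genes are included in the sum; users who want off-target spread only can
drop them from `per_node`.

## Ranking and selection

All candidates are scored with a fresh augmented network each (one flow
problem per candidate), sorted by flow descending with lexicographic ties.
The selected set is cut at `mean + z_{0.95} * sd` of the empirical flow
distribution (sample standard deviation, `tail = 0.05` configurable): a
one-sided upper-tail boundary under a normal fit, read as "the top-5% area
of the fitted distribution". Because real flow distributions are
right-skewed, more than 5% of candidates can exceed the cutoff; that is a
property of the construction, not an error.

## The worked example

```{r fixture}
fx <- worked_example_fixture()
fn <- build_flow_network(fx$network, "G1", fx$disease,
                         candidate_set = fx$candidates)
fr <- max_flow_push_relabel(fn)
fr$value
bfs_heights(fn)[["G1"]]
affected_genes_total(fr, fn)$per_node
fr$steps
```

The seven-gene fixture reconstructs the reference worked example from its
printed capacities (G1→G6 at 1.83, G1→G3 at 0.69, G3→G7 at 0.90). The full
original topology is not recoverable, so four directed padding arcs
(G4→G1, G2→G3, G2→G6, G5→G7) are added, chosen to (a) give G1, G3, G6 and
G7 in-degree 2 in the augmented network, matching the reference $K_i = 2$,
and (b) point *into* G1's reachable set so they cannot open an alternative
source-to-sink path — the test suite asserts by path enumeration that
every $S$–$T$ path uses one of the two printed arcs out of G1, which pins
the maximum flow at $1.83 + 0.69 = 2.52$. Whether the original figure's
$K_{G1}=2$ arose from the dummy arc plus one real edge cannot be
determined from the text; the fixture is built so both readings coincide.
The second candidate G2's reference values are not forced by any printed
capacity and are therefore not asserted anywhere.

## Baselines and evaluation

The comparison methods consume exactly the same network, candidate and
disease inputs as the flow ranking:

* **Degree**: incident links, a PPI pair counted once.
* **Entropy**: the cited degree-distribution measure leaves the exact
  formula open; we use the Shannon entropy of the normalized degrees of a
  node's neighbours, $H_i = -\sum_{j \in N(i)} p_j \log_2 p_j$ with
  $p_j = \deg(j)/\sum_{l \in N(i)} \deg(l)$ — 0 for a single neighbour,
  $\log_2 m$ for $m$ equal-degree neighbours.
* **Betweenness / closeness**: computed on arc distances $1/w$ (stronger
  coupling = shorter), zero-capacity arcs unusable; closeness is the
  reachable-only normalized form. These standard centralities are
  delegated to igraph; the distance convention is ours, since the weighting
  scheme only states that the same capacities are used.
* **Random walk with restart** (`alpha = 0.3`): capacity-proportional
  transitions, dangling mass returned to the restart node, iterated to an
  L1 change below $10^{-10}$; a candidate's score is the stationary mass
  on the disease genes (raw sum, not degree-normalized).
* **t-test**: Welch's unequal-variance statistic (robust to the unbalanced
  cancer/normal design), candidates ranked by $|t|$; groups with zero
  variance are handled with a machine-epsilon floor on the squared
  standard error.

Rankings are compared by interpolated average precision — at each attained
recall level, the maximum precision at or beyond it; mAP is the mean over
attained levels — and by the count and mean 1-based position of true
targets inside the top 1% / 3% / 15% windows
(`k = round(fraction * n)`, at least 1, `NA` position when the window is
empty). The interpolated mAP variant is stated here explicitly so users
comparing against other AP conventions can adjust.

`randomize_directions()` collapses each PPI pair to a single randomly
oriented arc, turning the partially directed network fully directed; with
`log_trend_fit()` (least squares on $y = a\ln x + b$ over the ranked
flows) one can reproduce the style of analysis showing that partial
directedness yields systematically higher flows than forced orientation.

## Preprocessing choices

Genes with more than 20% missing entries are removed (exactly 20% is
kept). Imputation is k-nearest-neighbours in the standard form of the
cited method: root-mean-square distance over mutually observed samples,
inverse-distance-weighted mean of the `k = 10` nearest genes observed at
the missing sample, exact-profile matches averaged directly; when fewer
than `k` neighbours exist, all available are used with a warning. The
reference protocol does not state `k` or the metric, so these defaults
are our interpretation, and correlations are computed *after* imputation
(also left open there); with the default 5% missingness the choice moves
individual correlations little. Upstream two-channel image processing and
replicate-spot collapsing are out of scope: the input contract is one
log2 ratio per gene per sample.

## The synthetic data generator

Real inputs at study scale (thousands of genes, tens of thousands of
interactions, curated disease and candidate sets) are not redistributable
here, so validation runs on `simulate_dataset()`. Its defaults are the
package's study conditions: 200 genes by 20 cancer + 15 normal samples,
four co-expression modules of 15 genes (a shared latent factor per module
over cancer samples, noise sd 0.35, module differential-expression shift
±1.5), 5% missingness, four planted targets wired by direct PPI edges to
the two disease genes of their module, and six decoy candidates built as
background hubs: ~13 links each to uncorrelated background genes plus one
weak link toward a disease gene. The construction guarantees planted
targets command high-capacity paths (within-module |correlation| ≈ 0.9,
|ΔE| ≈ 1.5 per endpoint) while decoys only have near-zero-correlation,
near-zero-ΔE routes, and simultaneously makes decoys the *degree* winners
— emulating the observation that hubs need not be good targets. The test
suite verifies at these sizes that the flow ranking recovers planted
targets ahead of decoys in at least 90% of 50 seeded replicates and beats
the degree baseline's mAP in the majority; solver cross-validation uses
200 random instances of up to 30 nodes. These problem sizes are the
package's validation scale, chosen so the full suite runs in well under a
minute.

What the generator does **not** emulate: array-level noise physics,
batch effects, realistic scale-free degree distributions, correlation
between modules, or annotation noise in the disease/candidate sets.
Passing recovery tests therefore demonstrates the method's mechanics —
that expression-weighted flow integrates path capacity the way it should
— not clinical performance on real cohorts.

## Limitations

* The affected-genes score inherits the non-uniqueness of flow
  decompositions; compare AG values only within one package version.
* All flow is computed per candidate independently; combination therapy
  (multi-source flow) is out of scope.
* Capacities are correlational; directed regulatory knowledge enters only
  through arc orientation, and regulatory arcs are weighted by the same
  co-expression formula as PPIs since no separate weighting is specified
  for them.
* Metabolic networks are excluded: their flux semantics would need kinetic
  parameters, not co-expression capacities.
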