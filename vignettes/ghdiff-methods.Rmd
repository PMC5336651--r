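---
title: "Detecting differential sub-networks with the Generalized Hamming Distance"
author: "ghdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential sub-networks with the Generalized Hamming Distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghdiff)
```

## The problem

Two biological conditions — say two tumour subtypes — induce two interaction
networks over the same set of genes. Most of the wiring is shared; a small
sub-network is rewired. `ghdiff` asks two questions: *are the two networks
statistically dependent at all?* and *which nodes belong to the rewired
(differential) part?* The intended regime is a pair of undirected networks on
an identical node set where the true difference touches a small fraction of
the edges.

## The statistic and its permutation null

Each graph is first converted to a symmetric matrix of pairwise connectivity
weights in $[0,1]$ — by default the cosine similarity of adjacency rows,
optionally the one-step topological overlap (the two are nearly collinear on
sparse graphs; `correlateMeasures()` quantifies this). With weights $a_{ij}$,
$b_{ij}$ centered by their own off-diagonal means ($a'$, $b'$), the
Generalized Hamming Distance is

$$\mathrm{GHD}(A,B) \;=\; \frac{1}{N(N-1)} \sum_{i \ne j} \big(a'_{ij} - b'_{ij}\big)^2 .$$

Under the null hypothesis that $A$ and $B$ are independent, relabelling $A$'s
nodes by a uniformly random permutation $\pi$ leaves the distribution of
$\mathrm{GHD}(A_\pi, B)$ unchanged, and that permutation distribution is
asymptotically normal with closed-form moments built from simple sums of the
weights ($S^1$, $S^2$, row-sum squares $T$, and the derived $A$, $B$, $C$
combinations). `nullMoments()` evaluates those formulas **on the centered
weights**. This choice matters: evaluated on raw weights the closed-form mean
is the exact permutation mean of the *uncentered* statistic, which differs
from the mean of the centered statistic by $(\bar a - \bar b)^2$. On centered
weights the mean is exact for the statistic actually computed (the package's
test suite verifies it against a 20,000-permutation Monte-Carlo oracle to
within Monte-Carlo error), and the variance — which is invariant to the
shift — agrees with the same oracle to a few percent.

The standardized score $z = (\mathrm{GHD} - \mu_\pi)/\sigma_\pi$ is referred
to $\mathcal N(0,1)$ and the test p-value is the **lower tail**,
$p = \Phi(z)$. Shared structure drives the GHD *below* its null mean, so
small $p$ means dependence; large $p$ means the independence of the two
(sub-)networks cannot be rejected — which, for a candidate sub-network, is
exactly what "differential" means. A sub-network needs $N \ge 4$ nodes for
the variance formula (factors $N-2$, $N-3$); that bound sets the default
`min_size = 4`.

## Per-node decomposition

Both the GHD and $\mu_\pi$ split into additive per-node shares
(`nodeContributions()`). The GHD share of node $i$ is its row's squared
centered difference; for the null-mean share the package uses

$$\mu_\pi(i) = \frac{\sum_{j\ne i} a'^2_{ij} + \sum_{j\ne i} b'^2_{ij}}{N(N-1)}
 - \frac{r^a_i S^1_b + r^b_i S^1_a}{N^2(N-1)^2},$$

with $r$ the centered row sums and $S^1$ the centered totals. The cross term
vanishes after centering, the shares sum *exactly* to $\mathrm{GHD}$ and
$\mu_\pi$ (a fuzz-tested invariant at $10^{-9}$ relative tolerance), and a
node's contribution to the centralized GHD
$\mathrm{cGHD} = \mathrm{GHD}-\mu_\pi$ collapses to
$-2\sum_{j \ne i} a'_{ij}b'_{ij} / (N(N-1))$: nodes whose weight rows agree
between the two networks contribute the most negative amounts. Alternative
double-counted cross-term conventions for $\mu_\pi(i)$ do not conserve the
totals, so conservation fixed this design choice.

## The detection algorithms

All three algorithms iteratively peel off the *least differential* node and
record the independence p-value of what remains; each removed node inherits
the p-value of the sub-network remaining immediately after its removal,
survivors inherit the terminal p-value, and Benjamini–Hochberg adjustment is
applied across all nodes. A node is called differential when its adjusted
p-value exceeds `alpha` (default 0.01). Sub-network weights are always
sub-selected from the full-network connectivity matrices — never recomputed
on induced subgraphs — while centering and moments are re-evaluated on every
sub-network; this keeps the per-node shares meaningful along the whole path
and each removal step costs $O(n)$ through incrementally maintained row
aggregates (the engine is tested to agree with naive full recomputation).

* **Closed-Form** (`closedForm()`): phase 1 computes the per-node
  contributions once on the full matrices, sorts ascending and removes nodes
  in that order, checking the p-value after every single removal, until
  $p > \theta$. Phase 2 then evaluates, for each remaining candidate, the
  exact cGHD of the sub-network with that candidate removed, and deletes the
  maximizer (the most similar remaining node), down to `min_size`.
* **Fast Approximation** (`fastApproximation()`): phase 1 instead scores
  every node once by the *estimated* post-removal cGHD — full-network cGHD
  minus the node's share — and removes in decreasing order of that estimate.
  Because subtracting a share inverts the contribution sort exactly, its
  ordered removal list is identical to Closed-Form's by construction (a
  tested invariant); the exact leave-one-out evaluation is reserved for
  phase 2, where both methods coincide.
* **dGHD baseline** (`dghdBaseline()`): the earlier single-phase greedy
  procedure driven by the *change* in cGHD caused by a removal. The raw
  difference of successive cGHD values carries a size-rescaling term from
  the shrinking $1/(n(n-1))$ normalisation that is common to every candidate
  and larger than a typical node share — ranking by the raw absolute
  difference would remove the *most* differential nodes first and invert the
  method — so the implemented criterion is the magnitude of the node's own
  share, recomputed at every iteration. Using the magnitude is what hurts
  this baseline on dense networks: strongly rewired nodes with large
  positive shares get discarded early (lower recall), which is the
  qualitative behaviour reported for it.

Ties in the contribution sort and in every argmax are broken by canonical
(lexicographic) node order, so runs are bit-reproducible.

### Choice of θ

`theta` separates the cheap sorted phase from the per-candidate phase. The
heuristic default is $10^{-50}$: `thetaSensitivity()` shows that on planted
permuted sub-networks the true-positive rate is already near its plateau
there and changes little as θ shrinks to $10^{-300}$ (the package asserts
the plateau on a 13-point grid). Larger θ switches to phase 2 earlier and
costs more; smaller θ risks sorting mistakes persisting longer.

## Ranking and evaluation

For threshold-free evaluation (`rocPr()`), nodes are ranked by adjusted
p-value with ties broken by removal order — later removal means more
differential, and survivors rank last (most differential). Exact remaining
ties count one half in the Mann–Whitney AUC. The PR curve uses step-wise
integration (precision held constant to the right of each recall increment)
to avoid the optimism of linear interpolation. Threshold metrics (precision,
recall, accuracy, specificity and Cohen's kappa on the $2\times2$ table) use
the differential call at `alpha`.

## The synthetic benchmarks

`makeInstance()` reproduces three planted-truth designs, with the first $k$
nodes in canonical order as gold standard:

* `rg_permuted` — a random geometric graph ($N$ uniform points on the unit
  square, edge iff distance $< d$; $d = 0.15$ sparse, $d = 0.3$ dense) whose
  first $k$ rows *and* columns are relabelled by one uniform permutation.
  Degrees are preserved; only the wiring of the planted block and its
  boundary changes.
* `rg_denser` — the entire network formed by the first $k$ nodes (internal
  block *and* crossing edges) is replaced by a fresh random geometric graph
  with radius $d' > d$. The block-only variant (crossing edges kept) is
  available via `replaceDenseSubnetwork(..., replace_incident = FALSE)`, but
  it anchors every planted node to hundreds of unchanged crossing edges and
  leaves the planted sub-network essentially undetectable by any of the
  methods, so the benchmark replaces the nodes' network wholesale — the
  regime in which a "densified module" is a meaningful planted truth.
* `pl_permuted` — a static scale-free graph (node $i$ weighted
  $\propto i^{-1/(\gamma-1)}$, endpoints drawn by weight, duplicates and
  self-loops rejected until exactly $E$ unique edges exist) with the first
  $k$ indices permuted. The degree-tail exponent is property-tested against
  a maximum-likelihood fit.

All generators draw from seeded streams (`withr::with_seed`), leave the
global RNG untouched, and derive the perturbation seed from the instance
seed by a fixed offset so the two draws do not share a stream. Multi-run
benchmarks use `base_seed + run`.

What the simulations do *not* emulate: weighted or signed edges, degree
assortativity of real regulatory networks, measurement noise in inferred
networks, and node sets that differ between conditions. Passing benchmarks
therefore demonstrates correctness of the statistics and algorithms under
the stated generative models, not performance on any particular inferred
biological network.

## Numerical choices and degenerate inputs

* The null variance is a difference of large terms; tiny negative values
  from cancellation are clipped to zero (warning beyond $-10^{-12}$).
* A degenerate null ($\sigma_\pi = 0$, e.g. constant weights) yields
  $p = 1$ when $\mathrm{GHD} \ge \mu_\pi$ and $p = 0$ otherwise, with a
  warning.
* Isolated nodes get cosine weight 0 by convention ($0/0 \to 0$); the
  topological overlap requires binary input and refuses weighted graphs.
* Benjamini–Hochberg p-values come from `stats::p.adjust`.
* Result TSVs keep full double precision (`%.17g`) so a written analysis
  round-trips bit-faithfully.

## Known limitations

* **Small-sub-network floor.** The normal approximation needs a few dozen
  nodes; as removals approach `min_size`, even an identical pair's terminal
  sub-networks drift to large p-values (phase 2 actively steers identical
  pairs toward constant-weight — hence degenerate — sub-matrices). A handful
  of terminal nodes can therefore always be called differential; calls
  outside the terminal tail are the meaningful ones, and the test suite pins
  exactly this behaviour.
* **The dGHD baseline is a reconstruction.** Its published description
  underdetermines the removal criterion; the implemented reading reproduces
  the reported qualitative behaviour (competitive on sparse networks, low
  recall on dense ones) but not every published summary number for the
  baseline, because the original's ranking internals are not recoverable.
* Exact permutation p-values are out of scope; the Monte-Carlo oracle lives
  only in the test suite.

## Problem sizes used by the checks

The package's own validation uses 250-graph pools at $N = 250$ for the
connectivity-measure comparison, 20 seeded runs at $N = 1000$, $k = 100$ for
each benchmark table row, 20 random weighted pairs at $N = 15$ with 20,000
permutations each for the moment oracle, 200 independent pairs at $N = 100$
for null calibration, 50 pairs for the order-identity property, and 25 runs
at $N = 250$ for the θ grid. These sizes were chosen once as the smallest
pools whose Monte-Carlo error is comfortably inside the assertion bands.

## A worked example

```{r example, eval = FALSE}
inst <- makeInstance(simulationSpec("rg_permuted", N = 250, d = 0.15,
                                    k = 50, seed = 7))
Wa <- cosineConnectivity(inst$graph_a)
Wb <- cosineConnectivity(inst$graph_b)
ghdTest(Wa, Wb)              # whole-network dependence test
res <- closedForm(Wa, Wb)    # differential sub-network detection
head(resultTable(res))
called <- callDifferential(res)
m <- classificationMetrics(confusionCounts(called, inst$gold,
                                           nodeLabels(Wa)))
rocPr(differentialScore(res), inst$gold, nodeLabels(Wa))$auc_roc
```
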