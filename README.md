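# ghdiff

Statistical detection of differential sub-networks between two undirected
networks that share a node set — e.g. gene-regulatory networks inferred for
two disease subtypes, where most wiring is common and a small module is
rewired.

## The method in brief

Each graph is converted to pairwise connectivity weights (cosine similarity
of adjacency rows by default, one-step topological overlap as an
alternative). The distance between the two weighted networks is the
Generalized Hamming Distance over mean-centered weights,

```
GHD(A, B) = 1/(N(N-1)) * Σ_{i≠j} (a'_ij − b'_ij)²,
```

whose distribution under uniform relabelling of one network (the
independence null) is asymptotically normal with closed-form mean and
variance computed from simple weight sums. The lower-tail p-value `Φ(z)` is
small when the networks share structure and large when independence cannot
be rejected. Both the GHD and its null mean decompose into additive per-node
shares, which drives three detection algorithms: **Closed-Form** (sort by
per-node contribution once, peel off the most-similar node until the
remaining sub-network's p-value exceeds θ = 1e-50, then switch to exact
per-candidate model selection), **Fast Approximation** (identical removal
order obtained from once-computed leave-one-out estimates) and a **dGHD**
baseline (greedy on the absolute per-node change in centralized GHD).
Removed nodes inherit the p-value of the remaining sub-network, p-values are
BH-adjusted, and nodes with adjusted p > α (default 0.01) are called
differential. Random geometric and static power-law generators with planted
differential sub-networks, plus confusion/kappa/ROC/PR evaluation and a
multi-run benchmark harness, reproduce the method's validation study.

## Worked example

```r
library(ghdiff)

# a 250-node random geometric network; B = A with its first 50 nodes permuted
inst <- makeInstance(simulationSpec("rg_permuted", N = 250, d = 0.15,
                                    k = 50, seed = 7))
Wa <- cosineConnectivity(inst$graph_a)
Wb <- cosineConnectivity(inst$graph_b)

ghdTest(Wa, Wb)
#> GHD test for network independence
#>   nodes: 250
#>   GHD = 0.0189468, null mean = 0.0549293, null sd = 0.00031384
#>   z = -114.7, p = 0 (lower tail; small p => dependent)

res <- closedForm(Wa, Wb)      # theta = 1e-50, alpha = 0.01
res
#> DiffNetResult (closed_form): 250 nodes, 70 called differential
#>   theta = 1e-50, alpha = 0.01; phase 1 removed 165, phase 2 removed 81, survivors 4

m <- classificationMetrics(confusionCounts(callDifferential(res),
                                           inst$gold, nodeLabels(Wa)))
unlist(m[c("precision", "recall", "kappa")])
#> precision    recall     kappa
#> 0.7000000 0.9800000 0.7608696

rocPr(differentialScore(res), inst$gold, nodeLabels(Wa))$auc_roc
#> [1] 0.9723
```

The whole-network test overwhelmingly rejects independence (the two graphs
share 200 untouched nodes), and the detection step recovers 49 of the 50
permuted nodes at the cost of 21 false positives; the AUC ranks nodes by
adjusted p-value with removal-order tie-breaking.

A thin command-line wrapper covers the same workflow
(`exec/ghdiff simulate | diff | evaluate | benchmark`); every run writes a
JSON echo of its effective configuration next to its output.

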