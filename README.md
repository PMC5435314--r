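# anatnet — anatomical network analysis of musculoskeletal systems

`anatnet` is an R package for **anatomical network analysis (AnNA)**: the
bones, muscles and fibrous knots (connective-tissue hubs from which more than
two aligned collagen-fiber bundles branch) of a musculoskeletal system are
modeled as typed nodes of an undirected simple graph, and their physical
contacts — joints, ligaments, monoaxial tendons — as edges. On that graph the
package answers the two questions AnNA asks of a limb: *which elements are
topologically central* and *how does the system decompose into modules*.

It is written for comparative morphologists and network biologists. The
package ships the 54-node musculoskeletal network of the frog hindlimb
(*Leptodactylus latinasus*; 27 muscles, 20 bones, 7 fibrous knots, 102
contacts, with its published five-module labeling) as a plain-CSV fixture,
and includes synthetic generators so every analysis stage is testable
without any download.

## What it computes

* **Betweenness centrality** (exact Brandes algorithm, unnormalized,
  unordered pairs): $C_B(v) = \sum_{\{s,t\}} \sigma_{st}(v)/\sigma_{st}$,
  the bridging role of each element in force propagation, plus a
  deterministic ranking and a brute-force path-enumeration oracle.
* **Modularity** $Q = \frac{1}{2m}\sum_{i,j}(A_{ij} - P_{ij})\,
  \delta(g_i,g_j)$ under three nulls: the standard configuration model
  $P_{ij} = k_ik_j/2m$; a **quasi-bipartite constrained null** that assigns
  zero expected mass to pairs of a forbidden node type (muscles never touch
  each other, so a realistic null must not penalize that) while preserving
  degree propensity and total edge mass; and a strict Barber-style
  bipartite null.
* **Modularity maximization**: exhaustive enumeration (exact, $n \le 12$)
  and a seeded multi-restart heuristic (greedy agglomeration + local-moving
  refinement with module splits and merges) for real systems.
* **Partition comparison** (adjusted Rand index, variation of information),
  **Fruchterman–Reingold layout** with a module-separation score,
  **degree-preserving rewiring** nulls, and generators of **limb-like
  quasi-bipartite** and **planted-partition** benchmark networks.

## Worked example

```r
library(anatnet)

net <- frog_hindlimb()
net
#> <anat_network: 54 nodes, 102 edges>
#>   types: bone=20, connective_knot=7, muscle=27
#>   published modules: Calf=3, Foot=16, Hip=9, Shank=12, Thigh=14

head(betweenness_centrality(net), 5)
#>   id                  name            type degree betweenness rank
#> 1 22                 Femur            bone     17    478.7579    1
#> 2 53           Tibiofibula            bone     15    447.2163    2
#> 3  1            Acetabulum            bone     14    248.1131    3
#> 4  3 Aponeurosis plantaris connective_knot      9    223.6939    4
#> 5 50               Tibiale            bone     10    217.2638    5

null <- build_null(net, "standard")
compute_Q(net, published_partition(net), null)
#> [1] 0.4926951

res <- best_partition(net, null, restarts = 20, seed = 1)
res
#> <module_search [best_partition]: Q = 0.492695, 5 modules>
compare_partitions(res, published_partition(net))$ari
#> [1] 1
```

Reading of the numbers: bones, not fibrous knots, dominate the centrality
ranking — the femur and tibiofibula are the system's main bridges, and nine
elements score above 100. The search recovers a five-module partition
(hip, thigh, shank, calf, foot complexes) with modularity 0.49, identical
(ARI = 1) to the published labeling, reflecting the limb's proximal-to-distal
modular organization.

The quasi-bipartite null is one call away:

```r
build_null(net, "constrained", forbidden_type = "muscle")
```

A command-line front end over the same functions lives at
`inst/scripts/anna.R` (subcommands `report`, `centrality`, `q`, `modules`,
`layout`, `simulate`).

## Package layout

| Path | Contents |
|---|---|
| `R/network.R`, `R/fixture.R` | graph model, validation, CSV/GraphML I/O, fixture |
| `R/centrality.R` | Brandes betweenness + enumeration oracle |
| `R/modularity.R` | null models, `compute_Q`, modularity matrix |
| `R/module_search.R` | exhaustive / greedy / local-moving search, ARI, VI |
| `R/layout.R` | Fruchterman–Reingold layout, separation score, plotting |
| `R/synthetic.R` | limb-like & planted generators, rewiring nulls |
| `R/report.R` | end-to-end `run_full_analysis()` |
| `vignettes/` | methods vignette: models, nulls, design choices |
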