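# overmod

Overlapping community detection for undirected networks — in particular
protein–protein interaction (PPI) networks — by a two-stage procedure
that converts any disjoint (hard) partition into an overlapping (soft)
partition through modularity optimisation.

## The problem and the model

Classical community detection assigns every node to exactly one module.
In interaction networks this hides an interesting class of proteins:
nodes that sit at module borders and mediate between functional units.
`overmod` starts from any hard partition (its own Louvain-style
optimiser, or a partition file produced by an external tool) and asks,
for every *connector* node — a node with at least one neighbour outside
its own module — whether the network's modularity improves when that
node belongs to several modules at once.

The objective is an overlapping extension of modularity.  For binary
assignment variables `x[i,m] ∈ {0,1}` (node `i` belongs to module `m`):

    Q_ov = Σ_m [ W_m / L  −  ( S_m / 2L )² ]

    S_m = Σ_i s_i x[i,m]           (sum of member strengths)
    W_m = Σ_{i≤j} a_ij x[i,m] x[j,m]  (edge weight inside module m)
    L   = total edge weight;  s_i = strength (weighted degree) of i

Nodes whose neighbours all lie in their own module (*isolated* nodes)
are frozen at their hard assignment — joining a module that contains
none of your neighbours adds to `S_m` without adding to `W_m` and can
only lower `Q_ov`.  Each connector must keep at least one membership
and may take any subset of its *candidate* modules (its own plus every
module it has a neighbour in), including leaving its original module.
The resulting nonconvex binary programme is solved by seeded
multi-start steepest-ascent local search (100 restarts by default,
exact enumeration available as an oracle on small instances).
Connectors that end up in ≥ 2 modules are *inter-connectors*; those
that stay in one are *intra-connectors*.

Around the core solver the package provides the evaluation machinery
used to study these node classes: the participation coefficient
`P_i = 1 − Σ_m (k_im / k_i)²`, per-node topological profiles, Jaccard
set stability, Monte-Carlo node-removal robustness curves `σ(N_r)`,
and a planted-overlap synthetic benchmark generator with recovery
scoring.

## Worked example

```r
library(overmod)

# two triangles {a,b,c} and {d,e,f} bridged by the edge c-d
edge_file <- tempfile()
writeLines(c("a b", "a c", "b c", "c d", "d e", "d f", "e f"), edge_file)
net <- read_edgelist(edge_file)
#> overmod network: 6 nodes, 7 edges (L = 7, 0 self-loops)

hp <- greedy_hard_partition(net, seed = 1)
hard_modularity(net, hp)
#> [1] 0.3571429                      # = 5/14 for the triangle partition

roles <- classify_nodes(net, hp)
#> overmod roles: 2 modules, 2 connectors, 4 isolated nodes

sp <- solve_exact(net, roles, hp)    # small enough to enumerate exactly
#> overmod soft partition: 6 nodes, Q_ov = 0.357143 (isolated=4 intra=2 inter=0)
```

The optimum keeps the hard partition: the bridge nodes `c` and `d` are
connectors but joining the opposite triangle would lower `Q_ov`
(`0.2398 < 0.3571`), so both stay intra-connectors.  Their profiles
show why — three edges each, only one of which crosses the border:

```r
node_profiles(net, hp, sp)[, c("node", "role", "degree", "participation")]
#>   node     role degree participation
#> 1    a isolated      2     0.0000000
#> 3    c    intra      3     0.4444444
#> 4    d    intra      3     0.4444444   (rows e, f as a)
```

On synthetic networks with planted overlapping nodes, recovery of the
planted multi-clustered set degrades as the mixing parameter grows:

```r
tab <- benchmark_suite(data.frame(mu = c(0.05, 0.3)),
                       replicates = 2, restarts = 10, seed = 42)
tab[, c("mu", "mean_jaccard", "mean_pred_size")]
#>     mu mean_jaccard mean_pred_size
#> 1 0.05    0.2538427          295.5
#> 2 0.30    0.1744273          424.0
```

`mean_jaccard` is the Jaccard index between the inter-connector set
found by the pipeline and the 75 planted overlapping nodes; both cells
sit well above the matched-size random baseline (≈ 0.14), and the
`mu = 0.05` cell beats the noisier `mu = 0.3` cell.

## Command line

A thin CLI wraps the same pipeline (see `inst/cli/overmod.R`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/overmod.R", package = "overmod"))')
Rscript $CLI pipeline --edges edges.tsv --auto-partition \
        --restarts 100 --seed 7 --out run1
```

writes `partition.tsv`, `soft.tsv`, `summary.tsv`, `profiles.tsv` and a
JSON `manifest.json` into `run1/`; every output starts with `#` headers
recording version, seed and parameters, and reruns are byte-identical.

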