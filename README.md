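# diffslc

Predicting essential proteins from a protein–protein interaction (PPI)
network by biasing centrality with gene coexpression and local edge
clustering.

## The problem and the method

Single-gene knockouts of some genes are lethal; identifying those
*essential* genes experimentally is expensive, and the
centrality–lethality observation — hub proteins in a PPI network are more
likely to be essential — makes network ranking an attractive computational
screen. Plain degree centrality, however, ignores two complementary signals:
how strongly two interacting proteins are *co-expressed*, and how embedded
an interaction is among its neighbors' interactions.

`diffslc` scores every protein `u` of an undirected simple PPI graph
`G = (V, E)` by combining three ingredients:

- **Edge clustering coefficient.** For an edge `(u, v)` with `z` triangles
  through it,

      ECC(u,v) = (z + 1) / min(k_u - 1, k_v - 1)

  with `k` the node degree, so the denominator is the largest number of
  triangles the edge could have; pendant edges score 0.

- **Gene coexpression.** A per-edge weight from the two endpoints'
  expression profiles: distance correlation (`dCor`, the default —
  non-negative, zero only under independence, sensitive to non-monotone
  dependence), Pearson, or Spearman.

- **Eigenvector centrality (EC).** The principal eigenvector of the
  adjacency matrix, which promotes low-degree proteins attached to
  important neighbors.

These mix through two parameters `β, ω ∈ [0, 1]`:

    BDC(u)     = Σ over incident edges e of [ β·coexpr(e) + (1-β)·ECC(e) ]
    DiffSLC(u) = ω·EC(u) + (1-ω)·BDC(u)

with defaults `β = 0.8`, `ω = 0.1`. The package also implements the
reference centralities the score is compared against (degree, harmonic
closeness, betweenness, eigenvector, subgraph), and a full
ranking-evaluation layer: ROC curves with trapezoid AUC (equal to the
Mann–Whitney statistic), precision–recall curves, confusion matrices at
top-k cutoffs, counts of (uniquely) detected essentials in the top 1–25%
of each ranking, overlap of two rankings' discoveries, and an AUC sweep
over the full `β × ω` grid.

Everything runs without downloads: a coupled fixture generator emulates the
whole input stack (MITAB 2.5 interactions, probeset × sample expression
matrix, annotation table, essential-gene list) with controllable
degree-linked essentiality and edge-level coexpression, in the exact
on-disk formats the readers consume.

## Worked example

```r
library(diffslc)

spec    <- fixture_spec(n_nodes = 500, seed = 42)   # synthetic yeast-like study
fx      <- simulate_fixture(spec)
net     <- fx$net
coexpr  <- edge_coexpression(net, fx$expr, fx$idmap, method = "dcor")
#> edge_coexpression: 32 of 1494 edge(s) lack usable profiles; set to 0
weights <- all_edge_weights(net, coexpr)
scores  <- diffslc(net, weights, beta = 0.8, omega = 0.1)
glance(scores)
#> # A tibble: 1 × 6
#>   method  n_nodes  beta omega normalization ec_mode
#>   <chr>     <int> <dbl> <dbl> <chr>         <chr>
#> 1 diffslc     500   0.8   0.1 ec_max        unweighted
head(tidy(scores), 3)
#> # A tibble: 3 × 3
#>   node  score  rank
#>   <chr> <dbl> <int>
#> 1 P0005  26.9     1
#> 2 P0001  13.4     2
#> 3 P0011  10.1     3
```

The 32 flagged edges have an endpoint without a usable probeset (the
generator plants deliberately unmapped proteins); they keep their ECC term
and a coexpression of 0. Ranks are deterministic: descending score, ties
broken by node identifier.

Evaluating the ranking against the planted essential set:

```r
labels <- label_nodes(net, fx$essentials)
glance(roc_curve(scores, labels))
#> # A tibble: 1 × 3
#>   kind  n_points   auc
#>   <chr>    <int> <dbl>
#> 1 roc        502 0.644
top_percent_hits(list(degree = degree_centrality(net), diffslc = scores),
                 labels, percents = c(10, 25))
#> # A tibble: 4 × 5
#>   method  percent n_top  hits unique_hits
#>   <chr>     <dbl> <dbl> <int>       <int>
#> 1 degree       10    50    21           1
#> 2 diffslc      10    50    21           1
#> 3 degree       25   125    38           1
#> 4 diffslc      25   125    45           8
```

An AUC of 0.644 means a randomly chosen essential protein outranks a
randomly chosen non-essential one 64% of the time; in the top quartile of
the ranking, the biased score finds 45 essentials, 8 of which degree
centrality misses at the same cutoff. `autoplot()` renders ROC/PR curves
and sweep heatmaps; `parameter_sweep()` maps AUC over the `β × ω` grid.

## Command line

A thin `Rscript` entry point wires the same functions into a five-stage
workflow with YAML configs and provenance-hashed TSV outputs:

```sh
exec/diffslc simulate --config run.yaml
exec/diffslc build    --config run.yaml     # filter, map IDs, weight edges
exec/diffslc rank     --config run.yaml --beta 0.8 --omega 0.1
exec/diffslc evaluate --config run.yaml
exec/diffslc sweep    --config run.yaml
```

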