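# radgrn

Correlation-network inference and spectral analysis of radiation-response
gene modules.

## The problem

Spaceflight transcriptome studies of *Arabidopsis thaliana* deliver
expression tables with very few replicate values per gene (3–8).  Detecting
which genes coordinate the DNA damage response (DDR) under ionizing
radiation from such data is done by network analysis rather than per-gene
statistics: a co-expression network is inferred, process modules are pulled
out, and the topology of those modules — who the hubs are, how tightly the
module is wired, how its spectrum looks — carries the biology.  `radgrn`
implements that workflow end-to-end for anyone analyzing small-replicate
expression matrices with a binary gene annotation (here: experimentally
determined radiation-induced ATR/ATM-responsive genes vs the rest), and
ships a synthetic-data generator so the whole pipeline is testable with no
downloads.

## The method

1. **GRN inference.** For every gene pair, the Pearson correlation
   r = cov(x, y) / (s_x s_y) is tested with t = r √((n−2)/(1−r²)) against
   Student t with n − 2 df (two-sided).  Edges with p ≤ 0.0005 (default;
   Bonferroni/BH optional) are kept with weight r.
2. **Subnetwork extraction.** Gene sets (GMT) are scored by one-sided
   hypergeometric over-representation on the network's connected gene list,
   with BH q-values across sets; enriched sets induce process subnetworks,
   and hubs are genes with total degree ≥ a threshold (working ranges 5–34
   at low radiation dose, 19–47 at very high dose).
3. **Network measures.** Degree distributions; subgraph centrality
   SC(i) = Σ_j u_j(i)² e^{λ_j} (the closed-walk sum — for the hub of a star
   with n leaves it is exactly cosh √n); adjacency spectral gap
   |λ₁| − |λ₂| and normalized random-walk gap 1 − |λ₂|; girth as the
   smallest r with Trace(Aʳ) > 0 on the directed view; diameter, average
   shortest path, components, density; Jaccard similarity of open gene
   neighborhoods within and across subnetworks; closeness, PageRank and
   eigenvector centrality.
4. **Causal discovery.** Per-gene Markov blankets by the incremental
   association (IAMB) algorithm — grow by maximal |partial correlation|
   given the current blanket, shrink by conditional-independence removal —
   using Fisher-z tests z = atanh ρ, statistic √(n−|Z|−3)·z; spouses are
   separated from parent/child neighbors by subset search, colliders orient
   children, everything else is reported `undetermined`.
5. **Gene ranking.** Logistic regression (IRLS, Wald p-values, odds
   ratios, ridge fallback on separation) of the binary gene label on five
   standardized centrality features; genes are ranked by fitted log-odds.

## Worked example

```r
library(radgrn)
cfg <- simulation_config(n_genes = 80, n_samples = 8, n_modules = 2,
                         module_sizes = c(10, 10), hub_leaf_counts = c(6, 6),
                         within_module_corr = 0.9,
                         frac_radiation_induced = 0.15, seed = 1)
res <- run_pipeline(pipeline_config(simulation = cfg), "demo_run")
head(res$enrichment, 3)
#>          set_name overlap set_size      p_value      q_value
#>  module_process_1      16       16 4.328190e-08 1.514867e-07
#>  module_process_2      16       16 4.328190e-08 1.514867e-07
#>   decoy_process_1       6       16 7.312112e-01 9.999442e-01
```

Both planted module processes are recovered far ahead of the decoys
(overlap 16/16 at q ≈ 1.5e-7).  The first subnetwork's summary:

```
nodes 16  edges 57  density 0.4750  diameter 3
spectral gap (adjacency) 5.3117  (normalized) 0.4815  components 1
```

and its ranking puts radiation-labeled genes on top (the planted labels are
hub-biased, so a correct fit must place them first):

```r
head(res$rankings[[1]], 5)
#>  rank      gene linear_score probability radiation
#>     1 AT3G00030     4.719970   0.9911633      TRUE
#>     2 AT3G00080     3.830095   0.9787537      TRUE
#>     3 AT5G00100     3.783216   0.9777566      TRUE
#>     4 AT4G00040     2.888212   0.9472606      TRUE
#>     5 AT1G00010     2.708050   0.9375000      TRUE
```

The star closed form is exact: the hub of a 12-leaf star has subgraph
centrality `cosh(sqrt(12))`:

```r
g <- igraph::make_star(13, mode = "undirected")
round(subgraph_centrality(g)[1], 4)
#> 15.9895
```

A command-line front end with the same stages is installed at
`system.file("cli", "radgrn", package = "radgrn")` (subcommands `simulate`,
`infer`, `extract`, `measure`, `jaccard`, `causal`, `rank`, `run`,
`report`).

## Documentation

The methods vignette (`vignettes/radgrn-methods.Rmd`) describes the model
assumptions, the synthetic-data generator and its limits, numerical
conventions (binarized vs weighted adjacency, tie handling, degenerate
inputs) and known limitations.
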