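# scnet

Cell-type-specific gene networks (CGNs) from annotated single-cell RNA-seq
counts, built under the guidance of a weighted reference interactome, plus
the network statistics needed to interpret them.

Differential expression tells you *which* genes a cell type expresses;
it says little about *what they do together*. `scnet` addresses the
complementary question — which parts of the known human gene network are
active in each cell population, and which genes organize them — for
computational biologists working with annotated scRNA-seq data and a
reference interactome such as HumanNet.

## What it computes

**Reference-guided CGN construction.** Counts are turned into a per-cell
rank-based inverse-normal gene activity score; the per-cell-type mean
activity is thresholded (default: retain the top 50% of genes), and a gene
pair is kept iff both genes pass *and* the pair is an edge of the
reference interactome. Retained edges carry the reference's
log-likelihood score (LLS) as weight.

**Bayesian link scoring.** A ranked link list *D* is evaluated against a
gold standard *L* in bins of 1 000 links:

    LLS = ln[ (P(L|D) / P(¬L|D)) / (P(L) / P(¬L)) ]

i.e. the log ratio of the posterior odds in the bin to the prior odds of
the pair space (`lls_curve()`).

**Hubness.** A gene's centrality is its *strength* — the sum of incident
edge LLS. `find_all_hubs()` compares each strength to a null distribution
pooled from degree-preserving edge rewirings of the network (weights
travel with edges; at least 10 000 pooled null scores), with BH-corrected
empirical p-values and FDR < 0.05 hub calls. Ribosomal proteins are
excluded from hub calls by default.

**Compactness.** `connectivity_test()` ranks a gene set's within-group
edge count against 10 000 random sets matched gene-by-gene to within
±20% of each real gene's degree — a topology-aware test of whether a
signature's genes work together in a given cell type's network.

**Differential centrality.** Strengths are converted to percentile ranks
(most central gene 1, least 0; genes absent from a network score 0) and

    diffPR_x = PR_{x,disease} − PR_{x,control}  ∈ [−1, 1].

`find_diff_hubs()` measures significance against one million pooled
diffPR values from permutations of the control network;
`top_diff_hubs()` keeps the top 5% of non-zero |diffPR|;
`classify_lost_gained()` labels hubs that cross the 0.7 percentile-rank
and |diffPR| gates as lost or gained in disease.

A synthetic-data module (`simulate_study()`) generates a modular
planted-partition interactome and negative-binomial, dropout-thinned
counts in which each cell type over-expresses one module, so the entire
pipeline is testable without downloads.

## Worked example

```r
library(scnet)

st  <- simulate_study(sim_config(), seed = 42)   # 300 genes, 6 modules, 3 cell types
act <- compute_activity(st$counts, st$annotation, min_cells = 50)
net <- build_cgn(act, st$reference, "alpha", threshold = 0.5)
net
#> # gene_network [alpha]: 150 nodes, 227 edges

glance(net)
#> # A tibble: 1 × 4
#>   n_nodes n_edges total_weight density
#> 1     150     227         457.  0.0203
```

Hub statistics against the rewiring null:

```r
hubs <- find_all_hubs(net, n_null = 10000, seed = 1)
head(tidy(hubs), 3)
#>   gene  strength percentile_rank p_value   fdr is_hub
#> 1 G009      23.3           1     0.00279 0.418 FALSE
#> 2 G038      21.1           0.993 0.0127  0.657 FALSE
#> 3 G014      20.8           0.987 0.0152  0.657 FALSE
```

`G009` has the largest summed LLS, but in this small modular network many
genes share similar degrees, so no gene clears FDR < 0.05 — the rewiring
null is doing its job.

Compactness of the six planted modules in the `alpha` network (cell type
`alpha` over-expresses module `M1`):

```r
mods <- st$modules[!is.na(st$modules$module), ]
conn <- connectivity_test(net, split(mods$gene, mods$module),
                          n_null = 1000, seed = 2)
tidy(conn)
#>   set   n_set n_in_network observed normalized  p_value evaluable
#> 1 M1       20           20       59      2.95  0.000999 TRUE
#> 2 M2       20            9       13      1.44  0.000999 TRUE
#> ...
```

All modules are compact relative to degree-matched random sets (they are
modules of the reference), but `M1` keeps all 20 genes in the network and
has by far the highest normalized connectivity: the planted signal.

Differential centrality after planting an 8-gene disease module:

```r
dz   <- simulate_disease_network(net, reference = st$reference, seed = 3)
diff <- find_diff_hubs(dz$network, net, n_null = 10000, seed = 4)
head(tidy(diff), 3)
#>   gene  pr_disease pr_control diff_pr p_value   fdr significant
#> 1 G054       0.943          0   0.943 0.00643 0.894 FALSE
#> 2 G161       0.930          0   0.930 0.0128  0.894 FALSE
#> 3 G103       0.924          0   0.924 0.0191  0.894 FALSE

top <- top_diff_hubs(diff)          # top 5% of non-zero |diffPR|
sum(dz$perturbed %in% top$gene)     # 8 of 8 planted genes recovered
#> [1] 8
```

Every result type has an `autoplot()` method (strength distributions,
null-vs-observed histograms, the diffPR histogram with the 0.7 gates).

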