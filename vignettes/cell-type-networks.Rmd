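---
title: "Cell-type-specific gene networks: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific gene networks: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

This vignette explains the statistical machinery behind `scnet`: what each
statistic assumes, which tunable parameters matter, and where the design was
genuinely open and why it was settled the way it was.

## The reference-guided model

A cell-type-specific gene network (CGN) is *not* inferred de novo from
co-expression. The model assumes a trusted weighted reference interactome —
an undirected gene graph whose edge weights are log-likelihood scores (LLS)
of functional linkage — and asks which part of it is *active* in a cell
population. A gene pair is a CGN edge iff

1. both genes pass an activity threshold in that cell population, and
2. the pair is an edge of the reference.

The retained edge keeps the reference LLS as its weight. This sidesteps the
noise floor of single-cell co-expression (sparsity, dropout, technical
variation) at the price of never discovering an interaction the reference
lacks — the central trade-off of reference-guided inference, and the reason
every downstream statistic is conditional on the reference.

## Gene activity: the transform and its rationale

The activity score feeding the threshold is deliberately simple and
parameter-free. Per cell: library-size normalize (counts per 10k),
`log1p`, then a rank-based inverse-normal transform across genes within the
cell, `qnorm(rank / (n_genes + 1))` with average ranks for ties. Per
stratum (cell type, or cell type × condition): the mean transformed value
over cells.

Design notes:

* Any monotone per-cell transform yields the same ranks, so the 10k scale
  factor is a convention, not a parameter.
* The within-cell rank-INT makes cells exchangeable regardless of depth or
  distributional shape; the cross-cell mean then rewards genes that are
  consistently high in the population rather than extreme in a few cells.
* All-zero genes are not an error: they receive the (tied) minimal rank's
  transform.
* Richer activity models (archetype or factor analyses) would capture
  substructure within a cell type; this transform intentionally trades that
  for determinism and auditability. The contract downstream code relies on
  is only "a standardized genes × strata activity matrix".

Thresholding defaults to `percentile` mode with `threshold = 0.5`: the
cutoff is the median of the stratum's activity column, i.e. the top 50% of
measured genes are retained. The retained fraction is exposed because no
principled universal value exists; lowering it strictly shrinks the network
(a tested monotonicity invariant). `min_cells = 50` guards the stratum
mean: below that, the mean of ~N(0,1) transformed values is too noisy for a
stable pass-set.

## Binned LLS evaluation

A ranked link list is scored against a gold standard of functional pairs in
bins (default 1 000 links, the final partial bin reported at its actual
size):

$$\mathrm{LLS} = \ln\frac{P(L\mid D)/P(\lnot L\mid D)}{P(L)/P(\lnot L)}$$

with the bin's positive/negative counts as the posterior odds and the
pair-space prior $P(L) = |L| / \binom{|U|}{2}$. Numerical decisions:

* The natural log is applied (the "log" in log-likelihood score); scores
  are in natural-log units.
* Ties in the data-intrinsic score are broken by lexicographic gene-pair
  order so binning is reproducible.
* Links with a gene outside the gold universe are *skipped*, not counted
  as negatives — counting unknowns as negatives would deflate
  $P(L\mid D)$ for well-annotated rankings.
* A bin with zero negatives (or positives) is reported as ±Inf and flagged
  `degenerate` rather than raising: early bins of a very good ranking
  legitimately contain only positives.

## The rewiring null for hubness

Strength (weighted degree, the sum of incident LLS) grows mechanically with
degree, so "is this gene a hub?" must be asked against networks with the
*same degree sequence*. The null is built by double-edge swaps — pick edges
(a,b), (c,d), rewire to (a,d), (c,b), reject self-loops and multi-edges —
with 10 × |E| swap attempts per replicate, enough to decorrelate graphs at
the sizes this package targets. Edge weights travel with the swapped edges,
preserving the total weight and the weight multiset; reshuffling weights
independently of topology is available (`shuffle_weights = TRUE`) but
non-default, because the LLS of an interaction is a property of the edge,
not of the network position.

Strengths of **all** genes across replicates are pooled until at least
`n_null = 10000` null scores accumulate. Pooling (rather than per-gene or
per-degree-class nulls) matches the statistic's interpretation — "is this
strength large for this network?" — and makes small networks affordable;
its cost is that genes sharing the top degrees shade each other, which is
visible in modular synthetic networks where no gene clears FDR < 0.05.
Empirical p-values carry a pseudo-count, $p = (1 + \#\{null \ge s\})/(1 +
|null|)$, so p is never exactly 0; BH correction runs across all tested
genes and the ribosomal exclusion list (symbol prefixes RPL/RPS/MRPL/MRPS,
user-overridable) only gates the final `is_hub` flag — excluded genes keep
their p-values.

Degenerate case: some graphs (stars) admit no valid swap. The rewiring
ensemble then contains only the observed configuration; `scnet` warns and
proceeds with that degenerate null instead of failing, so maximally
hub-like networks remain analysable. Networks with fewer than 3 edges are
rejected outright.

## Degree-matched compactness

`connectivity_test()` asks whether a gene set is unusually interconnected
*given its genes' degrees*. Each of `n_null = 10000` random sets matches
the real set gene-for-gene: the i-th sampled gene's unweighted degree lies
within ±20% of the i-th real gene's degree (interval bounds rounded
outward). Choices made where the source conventions are silent:

* Matching is positional ("for each real gene"), on unweighted degree;
  a weighted variant of the connectivity count is a non-default flag.
* Null sets may overlap the real set but may not equal it; sampling is
  without replacement within a set, with replacement across sets.
* The sampler first draws all positions independently (fast path) and
  falls back, for sets whose candidate pools overlap heavily, to a
  sequential draw that fills the tightest pools first with whole-set
  retries — the same support, but immune to deadlock near Hall's
  condition. A gene whose only admissible set is the real set itself is a
  hard error naming the gene and its degree.
* Observed connectivity is also reported normalized to the number of set
  genes present in the network, which is how compactness is compared
  across networks of different sizes; when several sets saturate the
  minimal attainable p (`1/(n_null+1)`), normalized connectivity is the
  tie-breaker.

The empirical p is the pseudo-counted rank of the observation in the null.
Because the statistic is an integer edge count, the test is slightly
conservative on very sparse networks (tie mass at the rejection boundary);
the package's calibration checks therefore use a moderately dense fixture
(80 nodes, edge probability 0.25, 12-gene sets) where the discreteness is
negligible and the nominal 5% level is recovered empirically.

## Differential centrality

Percentile ranks make centrality comparable across networks of different
sizes: $PR = (\mathrm{rank} - 1)/(n - 1)$ with minimum rank for ties (the
`dplyr::percent_rank()` convention), most central gene 1, least 0, and a
single-gene network scoring 1 by convention. Genes absent from a network's
node set score 0 there; a gene *in* the node set but isolated gets the PR
of strength 0 via min-rank — the absent-gene override applies only outside
the node set. Then $\mathrm{diffPR}_x = PR_{x,\mathrm{disease}} -
PR_{x,\mathrm{control}} \in [-1, 1]$.

`find_diff_hubs()` permutes the **control** network (degree-preserving
rewiring, consistent with the hub null; a node-label shuffle is an
alternative flag), recomputes every gene's diffPR against the fixed
disease network, and pools values until one million accumulate (tests and
the acceptance script scale this to 10⁴, which changes only the p-value
granularity). The p-value is two-sided on |diffPR|; BH runs over genes
with non-zero observed diffPR. One consequence of pooling: a gene absent
from the control contributes its own constant diffPR to every replicate,
so its attainable p is bounded below by roughly (replicates + 1)/(n_null +
1) — pooled nulls buy speed and a common scale at the price of per-gene
resolution.

`top_diff_hubs()` drops zero-diffPR genes, ranks by |diffPR| (ties broken
by gene name) and keeps the top 5% (ceiling). Lost/gained classification
uses 0.7 for both the PR gate and the |diffPR| threshold, reflecting the
clearly bimodal diffPR distribution of high-centrality genes; the
`autoplot()` histogram with the ±0.7 gates is the diagnostic to consult
before trusting that default on new data.

## The synthetic study

`simulate_study()` generates the conditions every statistic is validated
under:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 300 | simulated gene universe |
| `n_modules × module_size` | 6 × 20 | planted functional modules |
| `p_within` / `p_background` | 0.3 / 0.01 | planted-partition edge probabilities |
| edge weights | U(1, 3) | stand-in LLS |
| `cell_types` | 3 × 200 cells | cell type *i* over-expresses module *i* |
| `expression_effect` | 4 | fold-change of the planted module |
| `dropout_prob` | 0.5 | independent zero-inflation |
| `nb_dispersion` | 0.5 | counts ~ NB(mu, size = 1/0.5) |

Negative binomial + independent dropout is the minimal overdispersed
zero-inflated model; baseline means are log-normal (log-mean log 2, sd
0.5). The generator emulates sparsity, overdispersion, dropout and
module-structured signal. It does **not** emulate batch effects, doublets,
ambient RNA, trajectories, or degree distributions as heavy-tailed as the
real human interactome — so green tests here demonstrate correctness of
the statistics under their stated assumptions, not performance on real
tissue atlases.

The disease fixture plants an 8-gene module on top of a control network:
a clique over genes absent from the control CGN, with weights U(2, 3) (the
upper half of the simulated LLS range), emulating a tightly co-acting gene
program switched on by disease. The size is pathway-scale and deliberately
smaller than the expression modules: the top-5% differential-hub list over
a ~300-gene universe holds at most ~15 genes, so a recovery criterion
phrased against a 20-gene module could never be met by any implementation,
while an 8-gene planted program is squarely inside the statistic's
detection range. Full determinism per seed is asserted byte-for-byte in
the tests.

## Problem sizes and runtime

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a few minutes on one CPU: LLS
oracle checks on ≤ 200-link fixtures, rewiring nulls of 10⁴ pooled scores
on 30–80-node graphs, 300–500 calibration tests at `n_null` 500–1000,
differential nulls of 10⁴ pooled values, and ten end-to-end seeds of the
default 300-gene study. Defaults embedded in the API remain the full-scale
values (10⁴ hub scores, 10⁴ connectivity sets, 10⁶ diffPR values).

## Known limitations

* The activity transform is a documented stand-in for richer cell-state
  models; network sizes will not match pipelines that use archetype-based
  imputation.
* Everything is conditional on the reference interactome: biases of the
  reference (e.g. toward the ribosome, hence the default hub exclusion
  list) propagate to every CGN.
* Pooled nulls trade per-gene resolution for speed (see above).
* Gene identifiers are treated as opaque case-sensitive symbols; no alias
  or ID mapping is performed.
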