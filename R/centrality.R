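#' Weighted-degree centrality (strength)
#'
#' The centrality of a gene is the sum of the LLS weights of its incident
#' edges.  Tracked nodes without edges get strength 0.
#'
#' @param net A `gene_network`.
#' @return A tibble with columns `gene` and `strength`, sorted by gene.
#' @export
network_strength <- function(net) {
  net <- as_gene_network(net)
  if (length(network_nodes(net)) == 0L) {
    abort("the network has no nodes.")
  }
  idx <- network_index(net)
  tibble(gene = idx$nodes, strength = unname(index_strengths(idx)))
}

#' Percentile rank of centrality scores
#'
#' Maps scores to `[0, 1]` so networks of different sizes are comparable:
#' the most central gene gets 1 and the least central 0, via
#' `(rank - 1) / (n - 1)` with minimum rank for ties (the `dplyr`
#' `percent_rank()` convention).  A single score returns 1 by convention.
#'
#' @param x Numeric vector of centrality scores.
#' @return Numeric vector of percentile ranks in `[0, 1]`.
#' @export
#' @examples
#' percentile_rank(c(5, 3, 1))
percentile_rank <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(1)
  (rank(x, ties.method = "min") - 1) / (n - 1)
}

#' Hub genes against a degree-preserving rewiring null
#'
#' Tests every gene's weighted-degree centrality against a null distribution
#' obtained by rewiring the network ([rewire_network()]) and pooling the
#' strengths of all genes across replicates; replicates are added until at
#' least `n_null` null scores have accumulated.  Per-gene empirical p-values
#' use a pseudo-count (`p = (1 + #\{null >= strength\}) / (1 + |null|)`, so
#' p is never exactly 0), are BH-adjusted across all tested genes, and a
#' gene is a hub when `fdr < fdr_cut` and it is not excluded.  Ribosomal
#' proteins are excluded by default because the human interactome is biased
#' toward the ribosome complex.
#'
#' @param net A `gene_network` with at least 3 edges.
#' @param n_null Minimum pooled null size (default 10000).
#' @param fdr_cut BH FDR threshold for hub calls (default 0.05).
#' @param exclude Genes never reported as hubs (their p-values are still
#'   computed).  Default: [ribosomal_genes()] of the network's nodes.
#' @param shuffle_weights If `TRUE`, edge weights are reshuffled across
#'   edges in each replicate instead of traveling with the swapped edges
#'   (non-default alternative null).
#' @param n_swaps Swap attempts per replicate; default `10 * n_edges`.
#' @param seed Optional integer seed; results are deterministic given it.
#'
#' @return A tibble of class `hub_test` with columns `gene`, `strength`,
#'   `percentile_rank`, `p_value`, `fdr`, `is_hub`, sorted by decreasing
#'   strength.  The pooled null is kept in the `null` attribute.
#' @export
find_all_hubs <- function(net, n_null = 10000L, fdr_cut = 0.05,
                          exclude = NULL, shuffle_weights = FALSE,
                          n_swaps = NULL, seed = NULL) {
  net <- as_gene_network(net)
  if (nrow(net) < 3L) {
    abort("network too small for the hub test: need at least 3 edges.")
  }
  if (n_null < 1000L) {
    abort("`n_null` must be at least 1000 for a usable null distribution.")
  }
  idx <- network_index(net)
  if (is.null(exclude)) exclude <- ribosomal_genes(idx$nodes)
  n_swaps <- n_swaps %||% (10L * nrow(net))
  strength <- index_strengths(idx)

  null <- with_seed_if(seed, {
    reps <- ceiling(n_null / idx$n)
    pool <- vector("list", reps)
    for (r in seq_len(reps)) {
      pool[[r]] <- rewired_strengths(idx, n_swaps, shuffle_weights)
    }
    unlist(pool, use.names = FALSE)
  })

  p <- empirical_p_ge(null, unname(strength))
  fdr <- p.adjust(p, method = "BH")
  out <- tibble(
    gene = idx$nodes,
    strength = unname(strength),
    percentile_rank = percentile_rank(unname(strength)),
    p_value = p,
    fdr = fdr,
    is_hub = fdr < fdr_cut & !(idx$nodes %in% exclude)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$strength), .data$gene)
  structure(out,
            null = null,
            n_null = length(null),
            fdr_cut = fdr_cut,
            seed = seed,
            class = c("hub_test", class(out)))
}
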