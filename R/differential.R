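#' Differential percentile-rank centrality (diffPR)
#'
#' Because network size affects raw centrality, each gene's weighted degree
#' is converted to a percentile rank within its own network (most central
#' gene 1, least central 0; [percentile_rank()]), and the difference
#' \deqn{diffPR_x = PR_{x,disease} - PR_{x,control}}
#' is reported over the union of the two node sets.  A gene absent from a
#' network's node set gets PR 0 there, so diffPR spans `[-1, 1]` with
#' positive values meaning higher connectivity in the disease network.  A
#' gene that is in the node set but isolated gets the PR of strength 0
#' (minimum rank), not the absent-gene override.
#'
#' @param net_disease,net_control `gene_network`s for the two conditions.
#' @param universe Optional extra genes to report (absent from both
#'   networks, they get diffPR 0).
#' @return A tibble of class `diff_pr` with columns `gene`, `pr_disease`,
#'   `pr_control`, `diff_pr`, sorted by decreasing `diff_pr`.
#' @export
diff_pr <- function(net_disease, net_control, universe = NULL) {
  net_disease <- as_gene_network(net_disease)
  net_control <- as_gene_network(net_control)
  if (length(network_nodes(net_disease)) == 0L ||
      length(network_nodes(net_control)) == 0L) {
    abort("both networks must be nonempty.")
  }
  pr_d <- pr_lookup(net_disease)
  pr_c <- pr_lookup(net_control)
  genes <- sort(unique(c(names(pr_d), names(pr_c), universe)))
  prd <- ifelse(genes %in% names(pr_d), pr_d[genes], 0)
  prc <- ifelse(genes %in% names(pr_c), pr_c[genes], 0)
  out <- tibble(
    gene = genes,
    pr_disease = unname(prd),
    pr_control = unname(prc),
    diff_pr = unname(prd - prc)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$diff_pr), .data$gene)
  structure(out, class = c("diff_pr", class(out)))
}

# named PR vector over a network's node set
pr_lookup <- function(net) {
  s <- network_strength(net)
  stats::setNames(percentile_rank(s$strength), s$gene)
}

#' Permutation significance of differential centrality
#'
#' Builds a null distribution of diffPR values by randomly permuting the
#' control network — degree-preserving rewiring by default, consistent with
#' the hub test; `null_method = "label_shuffle"` permutes node labels
#' instead — recomputing every gene's diffPR against the fixed disease
#' network, and pooling values across genes and replicates until at least
#' `n_null` accumulate.  Each gene's two-sided empirical p-value compares
#' `|diffPR|` to the pooled null with a pseudo-count; BH correction is
#' applied over the genes with non-zero observed diffPR (zero-diffPR genes
#' get `fdr = NA`).
#'
#' @inheritParams diff_pr
#' @param n_null Minimum pooled null size (default one million).
#' @param fdr_cut BH FDR threshold for the `significant` flag.
#' @param null_method `"rewire"` (default) or `"label_shuffle"`.
#' @param n_swaps Swap attempts per rewired replicate; default
#'   `10 * n_edges` of the control network.
#' @param seed Optional integer seed.
#' @return A `diff_pr` tibble with extra columns `p_value`, `fdr`,
#'   `significant`; the pooled null is kept in the `null` attribute.
#' @export
find_diff_hubs <- function(net_disease, net_control, n_null = 1000000L,
                           fdr_cut = 0.05,
                           null_method = c("rewire", "label_shuffle"),
                           n_swaps = NULL, seed = NULL, universe = NULL) {
  null_method <- match.arg(null_method)
  net_disease <- as_gene_network(net_disease)
  net_control <- as_gene_network(net_control)
  if (nrow(net_control) < 3L) {
    abort("control network too small to permute: need at least 3 edges.")
  }
  obs <- diff_pr(net_disease, net_control, universe = universe)
  genes <- obs$gene
  idx_c <- network_index(net_control)
  n_swaps <- n_swaps %||% (10L * nrow(net_control))
  pr_d_vec <- obs$pr_disease
  in_control <- match(genes, idx_c$nodes)  # NA for genes absent from control

  null <- with_seed_if(seed, {
    reps <- ceiling(n_null / length(genes))
    pool <- vector("list", reps)
    for (r in seq_len(reps)) {
      s_c <- if (null_method == "rewire") {
        rewired_strengths(idx_c, n_swaps)
      } else {
        index_strengths(idx_c)[sample.int(idx_c$n)]
      }
      pr_c_rep <- percentile_rank(s_c)
      prc <- ifelse(is.na(in_control), 0, pr_c_rep[in_control])
      pool[[r]] <- pr_d_vec - prc
    }
    unlist(pool, use.names = FALSE)
  })

  p <- empirical_p_ge(abs(null), abs(obs$diff_pr))
  nonzero <- obs$diff_pr != 0
  fdr <- rep(NA_real_, length(p))
  fdr[nonzero] <- p.adjust(p[nonzero], method = "BH")
  out <- dplyr::mutate(as_tibble(obs),
                       p_value = p, fdr = fdr,
                       significant = !is.na(fdr) & fdr < fdr_cut)
  structure(out,
            null = null, n_null = length(null), fdr_cut = fdr_cut,
            null_method = null_method, seed = seed,
            class = c("diff_hub_test", "diff_pr", class(out)))
}

#' Top differential hubs by |diffPR|
#'
#' Drops genes with diffPR exactly 0, ranks the rest by decreasing
#' `|diffPR|` (ties broken by gene name for determinism) and returns the
#' top `ceiling(fraction * n)` records (default: top 5%).
#'
#' @param records A `diff_pr` tibble ([diff_pr()] or [find_diff_hubs()]).
#' @param fraction Top fraction in `(0, 1]`.
#' @return The selected rows, ordered by decreasing `|diffPR|`.
#' @export
top_diff_hubs <- function(records, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  keep <- records[records$diff_pr != 0, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  ord <- order(-abs(keep$diff_pr), keep$gene)
  keep[ord[seq_len(ceiling(fraction * nrow(keep)))], , drop = FALSE]
}

#' Classify lost and gained hubs between conditions
#'
#' A gene is a *lost* hub when it is highly central in the control network
#' (`pr_control > pr_cut`) and its diffPR drops by at least `diff_cut`
#' (`diff_pr <= -diff_cut`); symmetrically a *gained* hub is central in the
#' disease network with `diff_pr >= diff_cut`.  Genes passing neither PR
#' gate are `not_evaluated`; gated genes without a large enough change are
#' `unchanged`.  The default threshold 0.7 for both gates reflects the
#' clearly bimodal diffPR distribution of high-centrality genes; inspect it
#' with [autoplot.diff_pr()] before trusting the default on new data.
#'
#' @param records A `diff_pr` tibble.
#' @param pr_cut Percentile-rank gate in `(0, 1]`.
#' @param diff_cut `|diffPR|` threshold in `(0, 1]`.
#' @return `records` with a `class` column
#'   (`lost` / `gained` / `unchanged` / `not_evaluated`).
#' @export
classify_lost_gained <- function(records, pr_cut = 0.7, diff_cut = 0.7) {
  for (v in c(pr_cut, diff_cut)) {
    if (v <= 0 || v > 1) abort("thresholds must lie in (0, 1].")
  }
  cls <- dplyr::case_when(
    records$pr_control > pr_cut & records$diff_pr <= -diff_cut ~ "lost",
    records$pr_disease > pr_cut & records$diff_pr >= diff_cut ~ "gained",
    records$pr_control > pr_cut | records$pr_disease > pr_cut ~ "unchanged",
    TRUE ~ "not_evaluated"
  )
  dplyr::mutate(records, class = cls)
}
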