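# fixtures built in code; all randomness goes through explicit seeds

# Erdos-Renyi weighted network over n_nodes genes (all nodes tracked)
random_network <- function(n_nodes = 20, p = 0.3, seed = 1,
                           weight_range = c(1, 3)) {
  withr::with_seed(seed, {
    genes <- sprintf("N%03d", seq_len(n_nodes))
    i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
    j <- sequence((n_nodes - 1L):1L, from = 2L:n_nodes)
    keep <- stats::runif(length(i)) < p
    as_gene_network(
      tibble::tibble(
        gene_a = genes[i[keep]],
        gene_b = genes[j[keep]],
        weight = stats::runif(sum(keep), weight_range[1], weight_range[2])
      ),
      nodes = genes
    )
  })
}

# star K_{1,k}: center H connected to k leaves, unit weights
star_network <- function(k = 10, center = "HUB") {
  leaves <- sprintf("L%02d", seq_len(k))
  as_gene_network(
    tibble::tibble(gene_a = center, gene_b = leaves, weight = 1)
  )
}

# ring (2-regular) network with equal weights
ring_network <- function(n = 12, weight = 1) {
  genes <- sprintf("R%02d", seq_len(n))
  as_gene_network(
    tibble::tibble(
      gene_a = genes,
      gene_b = genes[c(2:n, 1L)],
      weight = weight
    )
  )
}

# sparse background plus a fully connected planted clique
planted_clique_network <- function(n_nodes = 60, p_bg = 0.05, k_clique = 8,
                                   seed = 1) {
  base <- random_network(n_nodes, p_bg, seed = seed)
  clique <- network_nodes(base)[seq_len(k_clique)]
  cmb <- utils::combn(clique, 2L)
  extra <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ], weight = 1)
  net <- as_gene_network(
    dplyr::bind_rows(tibble::as_tibble(base)[, c("gene_a", "gene_b", "weight")],
                     extra),
    nodes = network_nodes(base)
  )
  list(network = net, clique = clique)
}

# small study config so per-test simulation stays fast
small_sim_config <- function(...) {
  sim_config(
    n_genes = 60L, n_modules = 3L, module_size = 10L,
    p_within = 0.5, p_background = 0.03,
    cell_types = c(alpha = 60L, beta = 60L),
    ...
  )
}

# brute-force within-group edge counter (independent of the package path)
brute_connectivity <- function(net, genes) {
  df <- tibble::as_tibble(net)
  genes <- intersect(genes, network_nodes(net))
  if (length(genes) < 2) return(0L)
  cmb <- utils::combn(sort(genes), 2L)
  keys <- paste(cmb[1, ], cmb[2, ])
  edge_keys <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  sum(keys %in% edge_keys)
}

# brute-force per-bin LLS counter, written directly from the definition
brute_lls_bins <- function(links, gold, bin_size) {
  df <- tibble::as_tibble(links)[, 1:3]
  names(df) <- c("a", "b", "s")
  lo <- pmin(df$a, df$b); hi <- pmax(df$a, df$b)
  df$a <- lo; df$b <- hi
  df <- df[df$a != df$b, ]
  df <- df[order(-df$s, df$a, df$b), ]
  df <- df[!duplicated(paste(df$a, df$b)), ]
  df <- df[df$a %in% gold$universe & df$b %in% gold$universe, ]
  if (nrow(df) == 0) return(NULL)
  pos <- paste(df$a, df$b, sep = "\t") %in% gold$positives
  n_bins <- ceiling(nrow(df) / bin_size)
  do.call(rbind, lapply(seq_len(n_bins), function(bn) {
    rows <- seq((bn - 1) * bin_size + 1, min(bn * bin_size, nrow(df)))
    np <- sum(pos[rows]); nn <- length(rows) - np
    data.frame(bin = bn, n_links = length(rows), n_pos = np, n_neg = nn,
               lls = log((np / nn) / gold$prior_odds))
  }))
}

# unweighted degrees straight from the edge table
brute_degrees <- function(net) {
  nodes <- network_nodes(net)
  vapply(nodes, function(g) sum(net$gene_a == g) + sum(net$gene_b == g),
         integer(1))
}
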