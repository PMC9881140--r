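#' Degree-preserving rewiring of a weighted network
#'
#' Randomizes a network by repeated double-edge swaps: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b) (with random edge orientation),
#' rejecting any swap that would create a self-loop or a duplicate edge.
#' Every node keeps its exact unweighted degree, and each edge keeps its
#' weight (weights travel with the swapped edges), so the total edge weight
#' is preserved while the weight-to-node assignment is randomized.  This is
#' the null model behind [find_all_hubs()] and [find_diff_hubs()].
#'
#' Some graphs (e.g. stars) admit no valid swap; such networks are returned
#' unchanged with a warning, since the rewiring ensemble then contains only
#' the observed configuration.
#'
#' @param net A `gene_network` with at least 3 edges.
#' @param n_swaps Number of swap attempts; defaults to `10 * n_edges`,
#'   enough to decorrelate small graphs.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A rewired `gene_network` with the same nodes, degree sequence and
#'   multiset of edge weights.
#' @export
rewire_network <- function(net, n_swaps = NULL, seed = NULL) {
  net <- as_gene_network(net)
  if (nrow(net) < 3L) {
    abort("network too small to rewire: need at least 3 edges.")
  }
  idx <- network_index(net)
  n_swaps <- n_swaps %||% (10L * nrow(net))
  res <- with_seed_if(seed, rewire_index(idx, n_swaps))
  if (res$accepted == 0L) {
    warn("no valid edge swap exists; returning the network unchanged (degenerate rewiring ensemble).")
  }
  edges <- tibble(
    gene_a = idx$nodes[pmin(res$from, res$to)],
    gene_b = idx$nodes[pmax(res$from, res$to)],
    weight = res$weight
  )
  new_gene_network(
    dplyr::arrange(edges, .data$gene_a, .data$gene_b),
    nodes = idx$nodes,
    cell_type = attr(net, "cell_type", exact = TRUE),
    condition = attr(net, "condition", exact = TRUE),
    params = list(rewired = TRUE, n_swaps = n_swaps, seed = seed)
  )
}

# core double-edge-swap loop on the integer representation; RNG state is the
# caller's responsibility
rewire_index <- function(idx, n_swaps) {
  from <- idx$from
  to <- idx$to
  adj <- idx$adj
  n <- idx$n
  m <- length(from)
  accepted <- 0L
  key <- function(i, j) (pmin(i, j) - 1L) * n + pmax(i, j)
  for (k in seq_len(n_swaps)) {
    e <- sample.int(m, 2L)
    a <- from[e[1L]]; b <- to[e[1L]]
    c <- from[e[2L]]; d <- to[e[2L]]
    if (runif(1L) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (adj[key(a, d)] || adj[key(c, b)]) next
    adj[key(a, b)] <- FALSE
    adj[key(c, d)] <- FALSE
    adj[key(a, d)] <- TRUE
    adj[key(c, b)] <- TRUE
    from[e[1L]] <- a; to[e[1L]] <- d
    from[e[2L]] <- c; to[e[2L]] <- b
    accepted <- accepted + 1L
  }
  list(from = from, to = to, weight = idx$weight, adj = adj,
       nodes = idx$nodes, n = n, accepted = accepted)
}

# strengths of one rewired replicate (optionally with weights shuffled
# independently of the topology); used by the null builders
rewired_strengths <- function(idx, n_swaps, shuffle_weights = FALSE) {
  res <- rewire_index(idx, n_swaps)
  w <- res$weight
  if (shuffle_weights) w <- sample(w)
  s <- numeric(idx$n)
  tab <- rowsum(c(w, w), group = c(res$from, res$to))
  s[as.integer(rownames(tab))] <- tab[, 1]
  s
}
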