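#' Gene networks as tidy edge tables
#'
#' A `gene_network` is a tibble of undirected weighted edges with columns
#' `gene_a`, `gene_b` and `weight`, stored in canonical form: each pair is
#' ordered `gene_a < gene_b` lexicographically, rows are sorted by pair, and
#' there are no self-loops or duplicate pairs.  The node set is carried as an
#' attribute so that genes that passed an activity threshold but have no
#' retained edge are still tracked (they contribute strength 0 to centrality
#' statistics).
#'
#' @param x A data frame with at least three columns: the two interacting
#'   genes and a positive edge weight (the reference log-likelihood score).
#'   Extra columns are dropped.
#' @param nodes Optional character vector of node names; must contain every
#'   edge endpoint.  Defaults to the endpoints themselves.
#' @param cell_type,condition Optional labels recorded on the network.
#' @param params Optional named list of provenance parameters (recorded in
#'   file headers by [write_network()]).
#'
#' @return A tibble of class `gene_network` with columns `gene_a`, `gene_b`,
#'   `weight`.
#' @export
#' @examples
#' as_gene_network(data.frame(gene_a = "B", gene_b = "A", weight = 1.5))
as_gene_network <- function(x, nodes = NULL, cell_type = NULL,
                            condition = NULL, params = list()) {
  if (inherits(x, "gene_network") && is.null(nodes)) {
    return(x)
  }
  df <- as_tibble(x)
  if (ncol(df) < 3L) {
    abort("a gene network needs at least 3 columns: gene_a, gene_b, weight.")
  }
  df <- df[, 1:3]
  names(df) <- c("gene_a", "gene_b", "weight")
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$weight <- as.numeric(df$weight)
  if (anyNA(df)) {
    abort("gene network edges contain missing values.")
  }
  if (any(df$weight <= 0)) {
    abort("all edge weights must be > 0.")
  }
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warn(sprintf("dropped %d self-loop edge(s).", sum(self)))
    df <- df[!self, , drop = FALSE]
  }
  df <- canonicalise_pairs(df)
  dup <- duplicated(pair_key(df$gene_a, df$gene_b))
  if (any(dup)) {
    df <- df[!dup, , drop = FALSE]
  }
  df <- dplyr::arrange(df, .data$gene_a, .data$gene_b)
  endpoints <- union(df$gene_a, df$gene_b)
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(endpoints, nodes)
    if (length(missing) > 0L) {
      abort(sprintf("`nodes` is missing %d edge endpoint(s), e.g. %s.",
                    length(missing), missing[1]))
    }
  }
  new_gene_network(df, nodes = sort(nodes), cell_type = cell_type,
                   condition = condition, params = params)
}

new_gene_network <- function(edges, nodes, cell_type = NULL, condition = NULL,
                             params = list()) {
  structure(
    edges,
    nodes = nodes,
    cell_type = cell_type,
    condition = condition,
    params = params,
    class = c("gene_network", class(tibble()))
  )
}

#' Nodes of a gene network
#'
#' @param net A `gene_network`.
#' @return Sorted character vector of node names, including nodes without
#'   edges when those are tracked.
#' @export
network_nodes <- function(net) {
  nd <- attr(net, "nodes", exact = TRUE)
  if (is.null(nd)) sort(union(net$gene_a, net$gene_b)) else nd
}

#' @export
print.gene_network <- function(x, ...) {
  ct <- attr(x, "cell_type", exact = TRUE)
  cd <- attr(x, "condition", exact = TRUE)
  label <- if (!is.null(ct)) {
    paste0(" [", ct, if (!is.null(cd)) paste0(".", cd), "]")
  } else ""
  cat(sprintf("# gene_network%s: %d nodes, %d edges\n",
              label, length(network_nodes(x)), nrow(x)))
  NextMethod()
}

# keep the gene_network class (and node set) only when the edge schema
# survives a dplyr verb; otherwise fall back to a plain tibble
restore_network_attrs <- function(out, template) {
  if (all(c("gene_a", "gene_b", "weight") %in% names(out))) {
    new_gene_network(
      as_tibble(out),
      nodes = attr(template, "nodes", exact = TRUE),
      cell_type = attr(template, "cell_type", exact = TRUE),
      condition = attr(template, "condition", exact = TRUE),
      params = attr(template, "params", exact = TRUE)
    )
  } else {
    as_tibble(out)
  }
}

#' @export
`[.gene_network` <- function(x, ...) {
  restore_network_attrs(NextMethod(), x)
}

# unweighted degree per node (named integer vector over all tracked nodes)
node_degree <- function(net) {
  nodes <- network_nodes(net)
  d <- integer(length(nodes))
  names(d) <- nodes
  tab <- table(factor(c(net$gene_a, net$gene_b), levels = nodes))
  d[] <- as.integer(tab)
  d
}

# integer-indexed edge representation used by the rewiring machinery
network_index <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  if (n > 5000L) {
    abort("networks above 5000 nodes are not supported by the rewiring null.")
  }
  from <- match(net$gene_a, nodes)
  to <- match(net$gene_b, nodes)
  adj <- logical(n * n)
  adj[(pmin(from, to) - 1L) * n + pmax(from, to)] <- TRUE
  list(nodes = nodes, n = n, from = from, to = to,
       weight = net$weight, adj = adj)
}

# strengths (sum of incident weights) from an index representation
index_strengths <- function(idx, weight = idx$weight) {
  s <- numeric(idx$n)
  if (length(weight) > 0L) {
    tab <- rowsum(c(weight, weight), group = c(idx$from, idx$to))
    s[as.integer(rownames(tab))] <- tab[, 1]
  }
  names(s) <- idx$nodes
  s
}
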