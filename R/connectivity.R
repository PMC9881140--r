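#' Within-group connectivity of a gene set
#'
#' Counts the network edges with both endpoints inside the gene set
#' (members absent from the network are ignored).  With `weighted = TRUE`
#' the LLS weights of those edges are summed instead.
#'
#' @param net A `gene_network`.
#' @param genes Character vector of gene symbols.
#' @param weighted Sum edge weights instead of counting edges.
#' @return A single number: the edge count (or weight sum).
#' @export
within_group_connectivity <- function(net, genes, weighted = FALSE) {
  net <- as_gene_network(net)
  inside <- net$gene_a %in% genes & net$gene_b %in% genes
  if (weighted) sum(net$weight[inside]) else sum(inside)
}

#' Sample a degree-matched random gene set
#'
#' Draws a random set of network genes matching the degree profile of a
#' real set: for each real gene of unweighted degree d, the sampled gene has
#' degree within `[(1 - tolerance) d, (1 + tolerance) d]` (interval bounds
#' rounded outward to integers).  Genes are sampled without replacement
#' within one null set, by rejection with retries; a draw identical to the
#' real set is rejected.
#'
#' @param net A `gene_network`.
#' @param genes Real gene set (members absent from the network are ignored).
#' @param tolerance Relative degree tolerance (default 0.2, i.e. +/-20%).
#' @param max_retries Retries before giving up on a distinct draw.
#' @param seed Optional integer seed.
#' @return Character vector of sampled genes, same length as the matched
#'   real genes.
#' @export
sample_degree_matched_set <- function(net, genes, tolerance = 0.2,
                                      max_retries = 1000L, seed = NULL) {
  net <- as_gene_network(net)
  prep <- degree_match_prep(net, genes, tolerance)
  with_seed_if(seed, {
    draw <- draw_matched_sets(prep, 1L, max_retries)
    prep$nodes[draw[, 1L]]
  })
}

# precompute candidate pools per real gene for degree-matched sampling
degree_match_prep <- function(net, genes, tolerance) {
  deg <- node_degree(net)
  nodes <- names(deg)
  present <- intersect(unique(genes), nodes)
  if (length(present) == 0L) {
    abort("no member of the gene set is present in the network.")
  }
  target <- deg[present]
  pools <- lapply(seq_along(present), function(i) {
    d <- target[[i]]
    lo <- floor((1 - tolerance) * d)
    hi <- ceiling((1 + tolerance) * d)
    cand <- which(deg >= lo & deg <= hi)
    if (length(cand) == 0L) {
      abort(sprintf("no degree-matched candidate for gene '%s' (degree %d).",
                    present[i], d))
    }
    cand
  })
  list(nodes = nodes, present = present, target = unname(target),
       present_idx = match(present, nodes), pools = pools)
}

# draw `n_sets` degree-matched sets (columns of an index matrix), rejecting
# draws with repeated genes or identical to the real set.  Fast path: draw
# every position independently and keep the all-distinct rows; rows that
# fail fall back to a sequential without-replacement draw that fills the
# tightest candidate pools first (with whole-set retries on dead ends), so
# heavily overlapping pools cannot deadlock the sampler.
draw_matched_sets <- function(prep, n_sets, max_retries = 1000L) {
  k <- length(prep$pools)
  draws <- vapply(prep$pools, function(pool) {
    pool[sample.int(length(pool), n_sets, replace = TRUE)]
  }, integer(n_sets))
  draws <- matrix(draws, nrow = n_sets)  # n_sets x k
  real_sorted <- sort(prep$present_idx)
  bad <- function(row) {
    anyDuplicated(row) > 0L || identical(sort(row), real_sorted)
  }
  order_by_pool <- order(lengths(prep$pools))
  redo <- which(apply(draws, 1L, bad))
  for (i in redo) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      cand <- integer(k)
      used <- integer(0)
      dead <- FALSE
      for (pos in order_by_pool) {
        avail <- setdiff(prep$pools[[pos]], used)
        if (length(avail) == 0L) {
          dead <- TRUE
          break
        }
        pick <- avail[sample.int(length(avail), 1L)]
        cand[pos] <- pick
        used <- c(used, pick)
      }
      if (!dead && !identical(sort(cand), real_sorted)) {
        draws[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      i0 <- which.min(lengths(prep$pools))
      abort(sprintf(
        "could not draw a distinct degree-matched set after %d retries; gene '%s' (degree %d) has only %d candidate(s).",
        max_retries, prep$present[i0], prep$target[[i0]],
        length(prep$pools[[i0]])))
    }
  }
  t(draws)  # k x n_sets
}

#' Compactness test: within-group connectivity vs degree-matched null
#'
#' Measures how compact a gene set is inside a network: its observed
#' within-group connectivity is ranked against `n_null` random gene sets of
#' the same size whose genes match the real genes' degrees within
#' `tolerance` ([sample_degree_matched_set()]).  Significance is the rank of
#' the observation in the null with a pseudo-count,
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`.  The observed count is
#' also normalized to the number of set genes present in the network so
#' that compactness is comparable across networks of different sizes.
#'
#' @inheritParams sample_degree_matched_set
#' @param genes Character vector (one set), or a GMT tibble from
#'   [read_gmt()] / named list of character vectors for several sets.
#' @param n_null Number of null sets (default 10000).
#' @param weighted Use LLS-weighted connectivity (non-default).
#' @param set_name Label used in the output for a single character-vector
#'   set.
#'
#' @return A tibble of class `connectivity_test`, one row per set:
#'   `set`, `n_set`, `n_in_network`, `observed`, `normalized`, `p_value`,
#'   `evaluable`, plus a `null` list-column holding each set's null sample.
#'   Sets with fewer than 2 members in the network are flagged
#'   `evaluable = FALSE` with `p_value = NA` (never a silent `NaN`).
#' @export
connectivity_test <- function(net, genes, n_null = 10000L, tolerance = 0.2,
                              weighted = FALSE, max_retries = 1000L,
                              seed = NULL, set_name = NULL) {
  net <- as_gene_network(net)
  sets <- if (is.data.frame(genes)) {
    split(genes$gene, genes$set)
  } else if (is.list(genes)) {
    genes
  } else {
    stats::setNames(list(genes), set_name %||% "gene_set")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set_", seq_along(sets))
  }
  out <- with_seed_if(seed, {
    purrr::imap_dfr(sets, function(members, nm) {
      connectivity_test_one(net, unique(members), nm, n_null, tolerance,
                            weighted, max_retries)
    })
  })
  structure(out,
            n_null = n_null, tolerance = tolerance, seed = seed,
            class = c("connectivity_test", class(out)))
}

connectivity_test_one <- function(net, members, nm, n_null, tolerance,
                                  weighted, max_retries) {
  nodes <- network_nodes(net)
  present <- intersect(members, nodes)
  base <- tibble(
    set = nm,
    n_set = length(members),
    n_in_network = length(present)
  )
  if (length(present) < 2L) {
    warn(sprintf("set '%s' has %d gene(s) in the network; connectivity is not evaluable.",
                 nm, length(present)))
    return(dplyr::mutate(base, observed = within_group_connectivity(net, present, weighted),
                         normalized = NA_real_, p_value = NA_real_,
                         evaluable = FALSE, null = list(numeric(0))))
  }
  observed <- within_group_connectivity(net, present, weighted)
  prep <- degree_match_prep(net, present, tolerance)
  # adjacency over node indices for fast within-set counting
  idx <- network_index(net)
  wmat <- NULL
  if (weighted) {
    wmat <- matrix(0, idx$n, idx$n)
    lin <- (pmin(idx$from, idx$to) - 1L) * idx$n + pmax(idx$from, idx$to)
    wmat[lin] <- idx$weight
  }
  draws <- draw_matched_sets(prep, n_null, max_retries)  # k x n_null
  k <- nrow(draws)
  pi <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  pj <- sequence((k - 1L):1L, from = 2L:k)
  null <- vapply(seq_len(n_null), function(j) {
    s <- draws[, j]
    a <- s[pi]; b <- s[pj]
    lin <- (pmin(a, b) - 1L) * idx$n + pmax(a, b)
    if (weighted) sum(wmat[lin]) else sum(idx$adj[lin])
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_null)
  dplyr::mutate(base, observed = observed,
                normalized = observed / length(present),
                p_value = p, evaluable = TRUE, null = list(null))
}

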