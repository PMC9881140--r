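#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize scnet result objects
#'
#' `tidy()` returns the per-gene (or per-edge / per-set) table as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x A `gene_network`, `hub_test`, `connectivity_test`,
#'   `diff_pr` / `diff_hub_test`, or `cgn_set` object.
#' @param ... Unused.
#' @name scnet-tidiers
NULL

#' @rdname scnet-tidiers
#' @exportS3Method tidy gene_network
tidy.gene_network <- function(x, ...) {
  tibble(gene_a = x$gene_a, gene_b = x$gene_b, weight = x$weight)
}

#' @rdname scnet-tidiers
#' @exportS3Method glance gene_network
glance.gene_network <- function(x, ...) {
  n <- length(network_nodes(x))
  tibble(
    n_nodes = n,
    n_edges = nrow(x),
    total_weight = sum(x$weight),
    density = if (n > 1) nrow(x) / choose(n, 2) else NA_real_
  )
}

#' @rdname scnet-tidiers
#' @exportS3Method tidy hub_test
tidy.hub_test <- function(x, ...) {
  as_tibble(x)
}

#' @rdname scnet-tidiers
#' @exportS3Method glance hub_test
glance.hub_test <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_hubs = sum(x$is_hub),
    n_null = attr(x, "n_null", exact = TRUE),
    fdr_cut = attr(x, "fdr_cut", exact = TRUE)
  )
}

#' @rdname scnet-tidiers
#' @exportS3Method tidy connectivity_test
tidy.connectivity_test <- function(x, ...) {
  dplyr::select(as_tibble(x), -"null")
}

#' @rdname scnet-tidiers
#' @exportS3Method glance connectivity_test
glance.connectivity_test <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    n_null = attr(x, "n_null", exact = TRUE),
    tolerance = attr(x, "tolerance", exact = TRUE)
  )
}

#' @rdname scnet-tidiers
#' @exportS3Method tidy diff_pr
tidy.diff_pr <- function(x, ...) {
  as_tibble(x)
}

#' @rdname scnet-tidiers
#' @exportS3Method glance diff_pr
glance.diff_pr <- function(x, ...) {
  out <- tibble(
    n_genes = nrow(x),
    n_nonzero = sum(x$diff_pr != 0),
    max_abs_diff_pr = if (nrow(x) > 0) max(abs(x$diff_pr)) else NA_real_
  )
  if ("significant" %in% names(x)) {
    out$n_significant <- sum(x$significant)
    out$n_null <- attr(x, "n_null", exact = TRUE)
  }
  out
}

#' @rdname scnet-tidiers
#' @exportS3Method tidy cgn_set
tidy.cgn_set <- function(x, ...) {
  attr(x, "summary", exact = TRUE)
}
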