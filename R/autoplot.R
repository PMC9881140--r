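#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline labs
#'   theme_minimal geom_point after_stat
#' @export
ggplot2::autoplot

#' Plot methods for scnet results
#'
#' `autoplot()` gives each result type its standard diagnostic view:
#' the strength distribution of a network, a gene's observed strength
#' against the rewiring null for a hub test, the null connectivity
#' distribution with the observed value for a compactness test, and the
#' diffPR histogram (with the lost/gained thresholds) for differential
#' centrality — the view used to judge whether the default 0.7 threshold
#' matches the data's bimodality.
#'
#' @param object An scnet result object.
#' @param diff_cut Threshold lines drawn on the diffPR histogram.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name scnet-autoplot
NULL

#' @rdname scnet-autoplot
#' @exportS3Method autoplot gene_network
autoplot.gene_network <- function(object, bins = 30, ...) {
  s <- network_strength(object)
  ggplot(s, aes(x = .data$strength)) +
    geom_histogram(bins = bins, fill = "grey30") +
    labs(x = "weighted degree (sum of LLS)", y = "genes",
         title = "Network strength distribution") +
    theme_minimal()
}

#' @rdname scnet-autoplot
#' @exportS3Method autoplot hub_test
autoplot.hub_test <- function(object, bins = 40, ...) {
  null <- tibble(strength = attr(object, "null", exact = TRUE))
  obs <- as_tibble(object)
  ggplot(null, aes(x = .data$strength)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   fill = "grey70") +
    geom_point(data = obs,
               aes(x = .data$strength, y = 0, colour = .data$is_hub),
               shape = "|", size = 4) +
    labs(x = "weighted degree (sum of LLS)", y = "null density",
         colour = "hub",
         title = "Observed strengths vs rewiring null") +
    theme_minimal()
}

#' @rdname scnet-autoplot
#' @exportS3Method autoplot connectivity_test
autoplot.connectivity_test <- function(object, bins = 30, ...) {
  nulls <- tidyr::unnest(
    dplyr::select(as_tibble(object), "set", "null"),
    "null"
  )
  obs <- dplyr::select(as_tibble(object), "set", "observed")
  ggplot(nulls, aes(x = .data$null)) +
    geom_histogram(bins = bins, fill = "grey70") +
    geom_vline(data = obs, aes(xintercept = .data$observed),
               colour = "firebrick") +
    ggplot2::facet_wrap(~set, scales = "free") +
    labs(x = "within-group connectivity (degree-matched null)",
         y = "null sets",
         title = "Gene-set compactness vs degree-matched null") +
    theme_minimal()
}

#' @rdname scnet-autoplot
#' @exportS3Method autoplot diff_pr
autoplot.diff_pr <- function(object, diff_cut = 0.7, bins = 40, ...) {
  ggplot(as_tibble(object), aes(x = .data$diff_pr)) +
    geom_histogram(bins = bins, fill = "grey30") +
    geom_vline(xintercept = c(-diff_cut, diff_cut),
               linetype = "dashed", colour = "firebrick") +
    labs(x = "diffPR (disease - control)", y = "genes",
         title = "Differential percentile-rank centrality") +
    theme_minimal()
}
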