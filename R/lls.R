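#' Gold standard for Bayesian link evaluation
#'
#' A gold standard is a set of functionally linked gene pairs (positives)
#' over a declared gene universe.  Every unordered pair of universe genes
#' that is not a positive is treated as a negative, so the prior odds of a
#' link being functional are `P(L) / P(!L)` with
#' `P(L) = |positives| / choose(|universe|, 2)`.
#'
#' @param positives A data frame whose first two columns are the linked
#'   genes (order within a pair is ignored; duplicates and self-pairs are
#'   dropped).
#' @param universe Character vector of gene symbols defining the pair space;
#'   must contain every gene appearing in `positives`.
#'
#' @return An object of class `gold_standard` with elements `positives`
#'   (canonical pair keys), `universe`, `p_l` and `prior_odds`.
#' @export
#' @examples
#' gs <- gold_standard(data.frame(a = "G1", b = "G2"), c("G1", "G2", "G3"))
#' gs$prior_odds
gold_standard <- function(positives, universe) {
  universe <- sort(unique(as.character(universe)))
  if (length(universe) < 2L) {
    abort("the gold-standard universe needs at least 2 genes.")
  }
  pos <- as_tibble(positives)[, 1:2]
  names(pos) <- c("gene_a", "gene_b")
  pos$gene_a <- as.character(pos$gene_a)
  pos$gene_b <- as.character(pos$gene_b)
  pos <- pos[pos$gene_a != pos$gene_b, , drop = FALSE]
  outside <- setdiff(union(pos$gene_a, pos$gene_b), universe)
  if (length(outside) > 0L) {
    abort(sprintf("%d positive-pair gene(s) outside the universe, e.g. %s.",
                  length(outside), outside[1]))
  }
  keys <- unique(pair_key(pos$gene_a, pos$gene_b))
  n_pairs <- choose(length(universe), 2)
  p_l <- length(keys) / n_pairs
  if (p_l <= 0 || p_l >= 1) {
    abort("the gold-standard prior P(L) must lie strictly in (0, 1); supply a non-empty, non-exhaustive positive set.")
  }
  structure(
    list(positives = keys, universe = universe,
         p_l = p_l, prior_odds = p_l / (1 - p_l)),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("# gold_standard: %d positives over %d genes (P(L) = %.4g)\n",
              length(x$positives), length(x$universe), x$p_l))
  invisible(x)
}

#' Binned log-likelihood scores of a ranked link list
#'
#' Evaluates prioritized gene pairs against a gold standard with the
#' Bayesian log-likelihood score
#' \deqn{LLS = \ln\frac{P(L|D)/P(\neg L|D)}{P(L)/P(\neg L)}}
#' computed per bin of `bin_size` consecutive links after sorting by the
#' data-intrinsic score (descending; ties broken by lexicographic gene-pair
#' order so the binning is reproducible).  Links with either gene outside
#' the gold-standard universe cannot be called positive or negative and are
#' skipped before binning.  A bin with no negatives (or no positives) gets
#' an infinite LLS and is flagged `degenerate` rather than raising.
#'
#' @param links A data frame whose first three columns are gene A, gene B
#'   and the data-intrinsic score.  Self-pairs are dropped; duplicate
#'   unordered pairs keep their best-scoring occurrence.
#' @param gold A [gold_standard()].
#' @param bin_size Links per bin (default 1000); the final partial bin is
#'   reported with its actual size.
#'
#' @return A tibble with one row per bin: `bin`, `n_links`, `n_pos`,
#'   `n_neg`, `lls` (natural-log units), `degenerate`.
#' @export
lls_curve <- function(links, gold, bin_size = 1000L) {
  if (!inherits(gold, "gold_standard")) {
    abort("`gold` must be a gold_standard object.")
  }
  bin_size <- as.integer(bin_size)
  stopifnot_scalar_number(bin_size, "bin_size", lower = 1)
  df <- as_tibble(links)[, 1:3]
  names(df) <- c("gene_a", "gene_b", "score")
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$score <- as.numeric(df$score)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  df <- canonicalise_pairs(df)
  df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$gene_a, .data$gene_b)
  df <- df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
  evaluable <- df$gene_a %in% gold$universe & df$gene_b %in% gold$universe
  df <- df[evaluable, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(tibble(bin = integer(), n_links = integer(), n_pos = integer(),
                  n_neg = integer(), lls = double(), degenerate = logical()))
  }
  is_pos <- pair_key(df$gene_a, df$gene_b) %in% gold$positives
  bin <- (seq_len(nrow(df)) - 1L) %/% bin_size + 1L
  out <- tibble(bin = bin, pos = is_pos) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_links = dplyr::n(),
      n_pos = sum(.data$pos),
      n_neg = sum(!.data$pos),
      .groups = "drop"
    )
  out$lls <- log((out$n_pos / out$n_neg) / gold$prior_odds)
  out$degenerate <- !is.finite(out$lls)
  out
}
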