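#' Per-cell-type gene activity scores
#'
#' Transforms raw counts into a standardized genes-by-strata activity
#' matrix, the quantity thresholded when building cell-type networks.  Each
#' cell is library-size normalized (counts per 10k) and `log1p`-transformed,
#' then rank-based inverse-normal transformed across genes within the cell
#' (average ranks for ties, `qnorm(rank / (n_genes + 1))`), which removes
#' per-cell depth and distributional differences.  The activity of gene *g*
#' in a stratum is the mean transformed value over that stratum's cells.
#' Strata are cell types, or cell type x condition when the annotation has a
#' `condition` column.
#'
#' @param counts Genes x cells matrix (dense or `Matrix` sparse) of
#'   nonnegative counts with gene row names and cell column names.
#' @param annotation Data frame with `cell_id`, `cell_type` and optionally
#'   `condition`; every annotated cell must be a column of `counts`.
#' @param min_cells Strata with fewer cells are skipped with a warning
#'   (default 50; below that the mean activity is too noisy to threshold).
#'
#' @return A tibble of class `activity_matrix`: column `gene` plus one
#'   numeric column per retained stratum (named `celltype` or
#'   `celltype.condition`).  Attributes: `n_cells` (named integer vector),
#'   `strata` (tibble mapping column to cell type/condition), `skipped`.
#' @export
compute_activity <- function(counts, annotation, min_cells = 50L) {
  annotation <- as_tibble(annotation)
  for (col in c("cell_id", "cell_type")) {
    if (!col %in% names(annotation)) {
      abort(sprintf("`annotation` lacks required column '%s'.", col))
    }
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene row names and cell column names.")
  }
  missing <- setdiff(annotation$cell_id, colnames(counts))
  if (length(missing) > 0L) {
    abort(sprintf("%d annotated cell(s) absent from `counts`, e.g. '%s'.",
                  length(missing), missing[1]))
  }
  if (anyDuplicated(rownames(counts))) abort("gene ids must be unique.")
  if (anyDuplicated(colnames(counts))) abort("cell ids must be unique.")
  m <- as.matrix(counts)[, annotation$cell_id, drop = FALSE]
  if (any(m < 0)) abort("`counts` must be nonnegative.")
  n_genes <- nrow(m)

  # per-cell transform: depth-normalize, log1p, rank-INT across genes
  libsize <- colSums(m)
  libsize[libsize == 0] <- 1
  z <- vapply(seq_len(ncol(m)), function(j) {
    x <- log1p(m[, j] / libsize[j] * 1e4)
    qnorm(rank(x, ties.method = "average") / (n_genes + 1))
  }, numeric(n_genes))
  dimnames(z) <- dimnames(m)

  has_cond <- "condition" %in% names(annotation)
  strata_key <- if (has_cond) {
    paste(annotation$cell_type, annotation$condition, sep = ".")
  } else {
    annotation$cell_type
  }
  labels <- sort(unique(strata_key))
  sizes <- table(strata_key)[labels]
  keep <- as.integer(sizes) >= min_cells
  if (any(!keep)) {
    warn(sprintf("skipped %d stratum/strata with fewer than %d cells: %s",
                 sum(!keep), min_cells,
                 paste(labels[!keep], collapse = ", ")))
  }
  kept <- labels[keep]
  if (length(kept) == 0L) {
    abort("no stratum reaches `min_cells`; nothing to compute.")
  }
  act <- vapply(kept, function(lb) {
    rowMeans(z[, strata_key == lb, drop = FALSE])
  }, numeric(n_genes))
  out <- tibble(gene = rownames(m))
  for (lb in kept) out[[lb]] <- unname(act[, lb])

  strata <- tibble(
    label = kept,
    cell_type = if (has_cond) {
      vapply(strsplit(kept, ".", fixed = TRUE), `[[`, character(1), 1L)
    } else kept,
    condition = if (has_cond) {
      vapply(strsplit(kept, ".", fixed = TRUE), function(p) {
        paste(p[-1], collapse = ".")
      }, character(1))
    } else NA_character_
  )
  structure(
    out,
    n_cells = stats::setNames(as.integer(sizes[kept]), kept),
    strata = strata,
    skipped = labels[!keep],
    class = c("activity_matrix", class(out))
  )
}
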