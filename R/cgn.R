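#' Build one cell-type-specific gene network
#'
#' Reference-guided construction: genes whose activity in the chosen
#' stratum reaches the cutoff form the pass-set, and the network keeps
#' exactly the reference-interactome edges whose two endpoints both pass,
#' with the reference LLS as the edge weight.  In `percentile` mode the
#' cutoff is the `(1 - threshold)` quantile of the stratum's activity
#' column, i.e. `threshold` is the retained top fraction of genes (default
#' 0.5); in `absolute` mode the cutoff is `threshold` itself.
#'
#' @param activity An [`activity_matrix`][compute_activity].
#' @param reference A `gene_network` reference interactome.
#' @param cell_type Cell-type label (must match an activity column, together
#'   with `condition` if given).
#' @param condition Optional condition label.
#' @param threshold_mode `"percentile"` (default) or `"absolute"`.
#' @param threshold Retained top fraction in `(0, 1)` for percentile mode,
#'   or an absolute activity cutoff.
#'
#' @return A `gene_network` whose node set is the pass-set restricted to
#'   reference genes (so thresholded genes without retained edges still
#'   count as strength-0 nodes).
#' @export
build_cgn <- function(activity, reference, cell_type, condition = NULL,
                      threshold_mode = c("percentile", "absolute"),
                      threshold = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  label <- if (is.null(condition)) cell_type else paste(cell_type, condition, sep = ".")
  if (!label %in% names(activity)) {
    abort(sprintf("no activity column '%s'; available: %s.", label,
                  paste(setdiff(names(activity), "gene"), collapse = ", ")))
  }
  reference <- as_gene_network(reference)
  scores <- activity[[label]]
  if (threshold_mode == "percentile") {
    if (threshold <= 0 || threshold >= 1) {
      abort("percentile `threshold` must lie in (0, 1).")
    }
    cutoff <- quantile(scores, probs = 1 - threshold, names = FALSE, type = 7)
  } else {
    cutoff <- threshold
  }
  pass <- activity$gene[scores >= cutoff]
  ref_nodes <- network_nodes(reference)
  nodes <- intersect(pass, ref_nodes)
  keep <- reference$gene_a %in% pass & reference$gene_b %in% pass
  edges <- as_tibble(reference)[keep, c("gene_a", "gene_b", "weight")]
  if (length(nodes) == 0L) {
    warn(sprintf("empty pass-set for stratum '%s'; returning an empty network.",
                 label))
  }
  new_gene_network(
    dplyr::arrange(edges, .data$gene_a, .data$gene_b),
    nodes = sort(nodes),
    cell_type = cell_type,
    condition = condition,
    params = list(threshold_mode = threshold_mode, threshold = threshold,
                  cutoff = cutoff, n_pass = length(pass))
  )
}

#' Build cell-type networks for every annotated stratum
#'
#' Batch driver: computes activity once, then builds one network per
#' (cell type, condition) stratum present in the annotation.  Strata below
#' `min_cells` are skipped (reported in the summary, never aborting the
#' batch).  Optionally writes one edge-list file per network plus a
#' `summary.tsv`.
#'
#' @inheritParams compute_activity
#' @inheritParams build_cgn
#' @param out_dir Optional directory; when given, each network is written to
#'   `{celltype}[.{condition}].cgn.tsv` and the summary to `summary.tsv`.
#'
#' @return A named list of `gene_network`s (class `cgn_set`) with a
#'   `summary` attribute: one row per stratum with `label`, `cell_type`,
#'   `condition`, `n_cells`, `n_nodes`, `n_edges`, `status`.
#' @export
build_all_cgns <- function(counts, annotation, reference,
                           threshold_mode = c("percentile", "absolute"),
                           threshold = 0.5, min_cells = 50L, out_dir = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  act <- withCallingHandlers(
    compute_activity(counts, annotation, min_cells = min_cells),
    warning = function(w) {
      warn(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  strata <- attr(act, "strata", exact = TRUE)
  skipped <- attr(act, "skipped", exact = TRUE)
  n_cells <- attr(act, "n_cells", exact = TRUE)

  nets <- purrr::pmap(strata, function(label, cell_type, condition) {
    build_cgn(act, reference, cell_type = cell_type,
              condition = if (is.na(condition)) NULL else condition,
              threshold_mode = threshold_mode, threshold = threshold)
  })
  names(nets) <- strata$label

  summary <- dplyr::bind_rows(
    tibble(
      label = strata$label,
      cell_type = strata$cell_type,
      condition = strata$condition,
      n_cells = as.integer(n_cells[strata$label]),
      n_nodes = vapply(nets, function(n) length(network_nodes(n)), integer(1)),
      n_edges = vapply(nets, nrow, integer(1)),
      status = "built"
    ),
    if (length(skipped) > 0L) {
      tibble(label = skipped, cell_type = NA_character_,
             condition = NA_character_, n_cells = NA_integer_,
             n_nodes = NA_integer_, n_edges = NA_integer_,
             status = "skipped: below min_cells")
    }
  )
  summary <- dplyr::arrange(summary, .data$label)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lb in names(nets)) {
      write_network(nets[[lb]], file.path(out_dir, paste0(lb, ".cgn.tsv")))
    }
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  structure(nets, summary = summary, class = "cgn_set")
}

#' @export
print.cgn_set <- function(x, ...) {
  cat(sprintf("# cgn_set: %d network(s)\n", length(x)))
  print(attr(x, "summary", exact = TRUE))
  invisible(x)
}

#' Summary table of a set of cell-type networks
#'
#' @param object A `cgn_set` from [build_all_cgns()].
#' @param ... Unused.
#' @return The summary tibble (one row per stratum).
#' @export
summary.cgn_set <- function(object, ...) {
  attr(object, "summary", exact = TRUE)
}
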