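#' Load a weighted reference interactome from an edge-list file
#'
#' Reads a 2- or 3-column tab-separated edge list (`geneA  geneB  weight`),
#' auto-detecting an optional header line, and returns a validated
#' [gene_network][as_gene_network]: undirected, deduplicated, self-loops
#' dropped with a warning, all weights strictly positive.  The weight is the
#' reference log-likelihood score (LLS) and is the edge weight every
#' cell-type network built from this reference inherits.
#'
#' @param path Path to the edge-list file.
#' @param min_weight Optional lower bound; edges with weight below it are
#'   dropped (e.g. to emulate a stricter reference tier).
#' @param coding_genes Optional character vector (e.g. CCDS protein-coding
#'   symbols); edges with either endpoint outside it are dropped.
#' @param default_weight Weight assigned to every edge of a 2-column input;
#'   required in that case.
#'
#' @return A `gene_network`.
#' @export
load_interactome <- function(path, min_weight = NULL, coding_genes = NULL,
                             default_weight = NULL) {
  raw <- readr::read_lines(path)
  raw <- raw[!startsWith(raw, "#")]
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) abort(sprintf("'%s' contains no edges.", path))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (ncols[1] == 2L && is.null(default_weight)) {
    abort("2-column edge lists need `default_weight`.")
  }
  # header detection: a 3-column first row whose weight is not numeric
  start <- 1L
  if (ncols[1] >= 3L && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L
  }
  rows <- fields[seq(start, length(fields))]
  nc <- lengths(rows)
  bad <- which(!(nc %in% c(2L, 3L)))
  if (length(bad) > 0L) {
    abort(sprintf("malformed row at line %d of '%s': expected 2 or 3 fields, found %d.",
                  bad[1] + start - 1L, path, nc[bad[1]]))
  }
  ga <- vapply(rows, `[[`, character(1), 1L)
  gb <- vapply(rows, `[[`, character(1), 2L)
  w <- if (all(nc >= 3L)) {
    suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
  } else if (all(nc == 2L)) {
    rep(as.numeric(default_weight), length(rows))
  } else {
    abort(sprintf("'%s' mixes 2- and 3-column rows.", path))
  }
  if (anyNA(w)) {
    abort(sprintf("malformed row at line %d of '%s': weight is not numeric.",
                  which(is.na(w))[1] + start - 1L, path))
  }
  if (any(w <= 0)) {
    abort(sprintf("nonpositive weight at line %d of '%s'.",
                  which(w <= 0)[1] + start - 1L, path))
  }
  df <- tibble(gene_a = ga, gene_b = gb, weight = w)
  n0 <- nrow(df)
  if (!is.null(min_weight)) {
    df <- df[df$weight >= min_weight, , drop = FALSE]
    inform(sprintf("dropped %d edge(s) below min_weight = %g.",
                   n0 - nrow(df), min_weight))
  }
  if (!is.null(coding_genes)) {
    keep <- df$gene_a %in% coding_genes & df$gene_b %in% coding_genes
    if (any(!keep)) {
      inform(sprintf("dropped %d edge(s) with a non-coding endpoint.",
                     sum(!keep)))
    }
    df <- df[keep, , drop = FALSE]
  }
  as_gene_network(df, params = list(source = path))
}

#' Write / read a gene network as a deterministic edge-list file
#'
#' `write_network()` writes a canonical tab-separated edge list
#' (`gene_a  gene_b  weight`, pair-lexicographic row order) preceded by
#' comment header lines recording the package version and any provenance
#' parameters (including the seed) attached to the network, so every output
#' is reproducible from its header.  `read_network()` reads it back;
#' the two are exact inverses.
#'
#' @param net A `gene_network`.
#' @param path Output (input) file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `gene_network`.
#' @export
write_network <- function(net, path) {
  net <- as_gene_network(net)
  params <- attr(net, "params", exact = TRUE) %||% list()
  hdr <- c(
    sprintf("# scnet %s", as.character(utils::packageVersion("scnet"))),
    sprintf("# cell_type: %s", attr(net, "cell_type") %||% NA),
    sprintf("# condition: %s", attr(net, "condition") %||% NA),
    sprintf("# nodes: %s", paste(network_nodes(net), collapse = ",")),
    vapply(names(params), function(nm) {
      sprintf("# param %s: %s", nm, paste(format(params[[nm]]), collapse = ","))
    }, character(1))
  )
  body <- sprintf("%s\t%s\t%s", net$gene_a, net$gene_b,
                  format(net$weight, digits = 15, trim = TRUE, scientific = FALSE))
  readr::write_lines(c(hdr, "gene_a\tgene_b\tweight", body), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  nodes <- NULL
  node_line <- hdr[startsWith(hdr, "# nodes: ")]
  if (length(node_line) == 1L) {
    nodes <- strsplit(sub("^# nodes: ", "", node_line), ",", fixed = TRUE)[[1]]
  }
  grab <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ": "))]
    if (length(ln) != 1L) return(NULL)
    val <- sub(paste0("^# ", key, ": "), "", ln)
    if (identical(val, "NA")) NULL else val
  }
  df <- readr::read_tsv(I(body), col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    weight = readr::col_double()
  ))
  as_gene_network(df, nodes = nodes, cell_type = grab("cell_type"),
                  condition = grab("condition"))
}

#' Read annotated single-cell counts
#'
#' Reads either a Matrix Market sparse triplet file with `genes.tsv` and
#' `cells.tsv` sidecars, or a dense TSV (genes in rows, first column the
#' gene symbol) plus a cells TSV.  The cells file must contain a `cell_id`
#' column and the annotation column named by `celltype_col`; an optional
#' `condition_col` (e.g. disease/control) defines per-condition strata.
#'
#' @param counts_path Path to `.mtx` (sparse, genes x cells, 1-based indices)
#'   or a dense TSV.
#' @param genes_path For `.mtx` input: TSV whose first column is the gene
#'   symbol, one row per matrix row.
#' @param cells_path TSV with one row per cell.
#' @param celltype_col,condition_col Column names in the cells file.
#' @return A list with `counts` (a sparse `dgCMatrix`, genes x cells, with
#'   dimnames) and `annotation` (a tibble with `cell_id`, `cell_type` and
#'   optionally `condition`).
#' @export
read_expression <- function(counts_path, genes_path = NULL, cells_path,
                            celltype_col = "cell_type", condition_col = NULL) {
  cells <- readr::read_tsv(cells_path, col_types = readr::cols(.default = "c"))
  for (col in c("cell_id", celltype_col, condition_col)) {
    if (!col %in% names(cells)) {
      abort(sprintf("cells file '%s' lacks required column '%s'.",
                    cells_path, col))
    }
  }
  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(genes_path)) {
      abort("Matrix Market input needs `genes_path`.")
    }
    m <- methods::as(Matrix::readMM(counts_path), "CsparseMatrix")
    genes <- readr::read_tsv(genes_path, col_names = FALSE,
                             col_types = readr::cols(.default = "c"))[[1]]
    if (nrow(m) != length(genes)) {
      abort(sprintf("matrix has %d rows but genes file has %d entries.",
                    nrow(m), length(genes)))
    }
    if (ncol(m) != nrow(cells)) {
      abort(sprintf("matrix has %d columns but cells file has %d rows.",
                    ncol(m), nrow(cells)))
    }
    dimnames(m) <- list(genes, cells$cell_id)
  } else {
    dense <- suppressMessages(
      readr::read_tsv(counts_path, show_col_types = FALSE,
                      name_repair = "minimal")
    )
    genes <- as.character(dense[[1]])
    mat <- as.matrix(dense[, -1, drop = FALSE])
    rownames(mat) <- genes
    if (ncol(mat) != nrow(cells)) {
      abort(sprintf("matrix has %d columns but cells file has %d rows.",
                    ncol(mat), nrow(cells)))
    }
    if (!identical(colnames(mat), cells$cell_id)) {
      if (!setequal(colnames(mat), cells$cell_id)) {
        abort("cell ids in the counts header and cells file do not match.")
      }
      mat <- mat[, cells$cell_id, drop = FALSE]
    }
    m <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  }
  annotation <- tibble(
    cell_id = cells$cell_id,
    cell_type = cells[[celltype_col]]
  )
  if (!is.null(condition_col)) {
    annotation$condition <- cells[[condition_col]]
  }
  list(counts = m, annotation = annotation)
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then one gene per remaining
#' field.  `read_gmt()` returns a tidy long tibble with one row per
#' (set, gene); a line with a single member parses to a singleton set.
#'
#' @param path File path.
#' @param sets For `write_gmt()`: a tibble as returned by `read_gmt()`
#'   (columns `set`, `description`, `gene`) or a named list of character
#'   vectors.
#' @return `read_gmt()`: a tibble with columns `set`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("GMT line with fewer than 3 fields in '%s'.", path))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    tibble(set = parts[1], description = parts[2], gene = genes)
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  if (is.data.frame(sets)) {
    sets_list <- split(sets$gene, sets$set)
    desc <- tapply(sets$description, sets$set, `[[`, 1L)
  } else {
    sets_list <- sets
    desc <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  nms <- sort(names(sets_list))
  lines <- vapply(nms, function(nm) {
    paste(c(nm, unname(desc[nm]), sets_list[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path File path; lines starting with `#` and blank lines are
#'   skipped.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Ribosomal-protein genes by symbol prefix
#'
#' The human interactome is strongly biased toward the ribosome, so hub
#' calling excludes ribosomal proteins by default.  Membership is decided by
#' symbol prefix (`RPL`, `RPS`, `MRPL`, `MRPS`, bundled in
#' `inst/extdata/ribosomal_prefixes.txt` and user-overridable).
#'
#' @param genes Character vector of gene symbols to filter.
#' @param prefixes Character vector of symbol prefixes; defaults to the
#'   bundled list.
#' @return The subset of `genes` matching any prefix.
#' @export
#' @examples
#' ribosomal_genes(c("RPL3", "TP53", "MRPS12"))
ribosomal_genes <- function(genes, prefixes = NULL) {
  if (is.null(prefixes)) {
    path <- system.file("extdata", "ribosomal_prefixes.txt", package = "scnet")
    prefixes <- read_gene_list(path)
  }
  hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(genes, p)))
  genes[hit %||% rep(FALSE, length(genes))]
}
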