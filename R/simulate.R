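#' Configuration for the synthetic study generator
#'
#' The generator emulates the statistical structure the network statistics
#' assume: a sparse reference interactome containing dense functional
#' modules (a planted-partition graph), and overdispersed zero-inflated
#' single-cell counts in which each annotated cell type over-expresses one
#' planted module.  Defaults: 300 genes, 6 modules of 20, within-module
#' edge probability 0.3 vs background 0.01, three cell types of 200 cells,
#' 4-fold module over-expression, 50% dropout, NB dispersion 0.5.
#'
#' @param n_genes Total simulated genes.
#' @param n_modules,module_size Planted functional modules (must fit into
#'   `n_genes`).
#' @param p_within,p_background Edge probabilities inside modules and in the
#'   background.
#' @param cell_types Named integer vector: cells per cell type.  Cell type
#'   i over-expresses module i (recycled if more cell types than modules).
#' @param expression_effect Fold-change (> 1) of a cell type's planted
#'   module genes.
#' @param dropout_prob Independent dropout (zeroing) probability in `[0, 1]`.
#' @param nb_dispersion Negative-binomial dispersion (> 0); counts are
#'   `NB(mu, size = 1/dispersion)`.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L, n_modules = 6L, module_size = 20L,
                       p_within = 0.3, p_background = 0.01,
                       cell_types = c(alpha = 200L, beta = 200L, gamma = 200L),
                       expression_effect = 4, dropout_prob = 0.5,
                       nb_dispersion = 0.5) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    p_within = p_within, p_background = p_background,
    cell_types = cell_types, expression_effect = expression_effect,
    dropout_prob = dropout_prob, nb_dispersion = nb_dispersion
  )
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("n_modules * module_size must not exceed n_genes.")
  }
  for (p in c("p_within", "p_background", "dropout_prob")) {
    stopifnot_scalar_number(cfg[[p]], p, lower = 0, upper = 1)
  }
  stopifnot_scalar_number(cfg$expression_effect, "expression_effect", lower = 1)
  stopifnot_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 1e-8)
  if (is.null(names(cfg$cell_types)) || any(!nzchar(names(cfg$cell_types)))) {
    names(cfg$cell_types) <- paste0("ct", seq_along(cfg$cell_types))
  }
  structure(cfg, class = "sim_config")
}

# gene ids G001, G002, ... with widths adapted to n_genes
sim_gene_ids <- function(n) {
  sprintf(paste0("G%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' Simulate a modular reference interactome
#'
#' Planted-partition graph over `n_genes` genes: unordered pairs inside a
#' module are edges with probability `p_within`, all other pairs with
#' probability `p_background`; edge weights (stand-in LLS) are drawn
#' Uniform(1, 3).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; output is fully deterministic given it.
#' @return A list: `network` (a `gene_network` whose node set is all
#'   simulated genes) and `modules` (tibble `gene`, `module`, with `NA`
#'   module for background genes).
#' @export
simulate_reference <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg$n_genes)
  module <- rep(NA_character_, cfg$n_genes)
  in_mod <- seq_len(cfg$n_modules * cfg$module_size)
  module[in_mod] <- paste0("M", rep(seq_len(cfg$n_modules),
                                    each = cfg$module_size))
  # all unordered pairs (i < j)
  i <- rep(seq_len(cfg$n_genes - 1L), times = (cfg$n_genes - 1L):1L)
  j <- sequence((cfg$n_genes - 1L):1L, from = 2L:cfg$n_genes)
  same <- !is.na(module[i]) & !is.na(module[j]) & module[i] == module[j]
  edges <- with_seed_if(seed, {
    keep <- runif(length(i)) < ifelse(same, cfg$p_within, cfg$p_background)
    tibble(
      gene_a = genes[i[keep]],
      gene_b = genes[j[keep]],
      weight = runif(sum(keep), 1, 3)
    )
  })
  net <- as_gene_network(edges, nodes = genes,
                         params = list(seed = seed, p_within = cfg$p_within,
                                       p_background = cfg$p_background))
  list(network = net, modules = tibble(gene = genes, module = module))
}

#' Simulate annotated single-cell counts with planted modules
#'
#' Gene baseline means are log-normal; counts are negative binomial
#' (`mu`, `size = 1/nb_dispersion`) with the planted module of each cell
#' type multiplied by `expression_effect`, followed by independent dropout
#' zeros with probability `dropout_prob`.
#'
#' @inheritParams simulate_reference
#' @param modules Module map from [simulate_reference()].
#' @return A list: `counts` (sparse genes x cells `dgCMatrix`) and
#'   `annotation` (tibble `cell_id`, `cell_type`).
#' @export
simulate_counts <- function(cfg, modules, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- modules$gene
  n_genes <- length(genes)
  ct_names <- names(cfg$cell_types)
  mods <- paste0("M", seq_len(cfg$n_modules))
  planted <- mods[((seq_along(ct_names) - 1L) %% cfg$n_modules) + 1L]
  names(planted) <- ct_names

  out <- with_seed_if(seed, {
    mu0 <- rlnorm(n_genes, meanlog = log(2), sdlog = 0.5)
    cols <- lapply(ct_names, function(ct) {
      boost <- ifelse(!is.na(modules$module) &
                        modules$module == planted[[ct]],
                      cfg$expression_effect, 1)
      mu <- mu0 * boost
      n_cells <- cfg$cell_types[[ct]]
      cnt <- matrix(
        rnbinom(n_genes * n_cells, mu = mu, size = 1 / cfg$nb_dispersion),
        nrow = n_genes
      )
      drop <- matrix(
        rbinom(n_genes * n_cells, 1L, cfg$dropout_prob) == 1L,
        nrow = n_genes
      )
      cnt[drop] <- 0L
      cnt
    })
    do.call(cbind, cols)
  })
  cell_type <- rep(ct_names, times = as.integer(cfg$cell_types))
  cell_ids <- sprintf(paste0("C%0", max(4L, nchar(length(cell_type))), "d"),
                      seq_along(cell_type))
  dimnames(out) <- list(genes, cell_ids)
  list(
    counts = methods::as(Matrix::Matrix(out, sparse = TRUE), "CsparseMatrix"),
    annotation = tibble(cell_id = cell_ids, cell_type = cell_type)
  )
}

#' Gold standard from the planted modules
#'
#' Positives are all within-module gene pairs; the universe is every
#' simulated gene, mirroring a functional gold standard over a modular
#' interactome.
#'
#' @param modules Module map from [simulate_reference()].
#' @return A [gold_standard()].
#' @export
simulate_gold_standard <- function(modules) {
  mod <- modules[!is.na(modules$module), , drop = FALSE]
  pairs <- purrr::map_dfr(split(mod$gene, mod$module), function(g) {
    if (length(g) < 2L) return(tibble(gene_a = character(), gene_b = character()))
    cmb <- utils::combn(sort(g), 2L)
    tibble(gene_a = cmb[1L, ], gene_b = cmb[2L, ])
  })
  if (nrow(pairs) == 0L) {
    abort("no within-module pair exists (module_size < 2); the gold-standard prior is undefined.")
  }
  gold_standard(pairs, universe = modules$gene)
}

#' Plant a perturbed disease module on top of a control network
#'
#' Returns a disease-condition copy of the control network with one extra
#' densely connected module: a clique over `n_perturb` genes drawn from
#' `candidates` (by default, reference genes absent from the control
#' network, emulating a gene program switched on by disease), with strong
#' stand-in LLS weights drawn Uniform over `weight_range`.  Used to
#' validate differential-centrality recovery end to end.
#'
#' @param control A `gene_network` (the control-condition network).
#' @param candidates Genes eligible for the perturbed module; defaults to
#'   genes of `reference` not in the control node set.
#' @param reference Optional reference network supplying `candidates`.
#' @param n_perturb Size of the perturbed module (default 8).
#' @param weight_range Range of the planted edge weights (default 2-3, the
#'   upper half of the simulated LLS range).
#' @param seed Integer seed.
#' @return A list: `network` (the disease `gene_network`) and `perturbed`
#'   (character vector of the planted module's genes).
#' @export
simulate_disease_network <- function(control, reference = NULL,
                                     candidates = NULL, n_perturb = 8L,
                                     weight_range = c(2, 3), seed = 1L) {
  control <- as_gene_network(control)
  if (is.null(candidates)) {
    if (is.null(reference)) {
      abort("supply either `candidates` or `reference`.")
    }
    candidates <- setdiff(network_nodes(reference), network_nodes(control))
  }
  if (length(candidates) < n_perturb) {
    abort(sprintf("only %d candidate gene(s) for a %d-gene perturbed module.",
                  length(candidates), n_perturb))
  }
  out <- with_seed_if(seed, {
    picked <- sort(sample(candidates, n_perturb))
    cmb <- utils::combn(picked, 2L)
    extra <- tibble(
      gene_a = cmb[1L, ], gene_b = cmb[2L, ],
      weight = runif(ncol(cmb), weight_range[1], weight_range[2])
    )
    list(picked = picked, extra = extra)
  })
  disease <- as_gene_network(
    dplyr::bind_rows(as_tibble(control)[, c("gene_a", "gene_b", "weight")],
                     out$extra),
    nodes = union(network_nodes(control), out$picked),
    cell_type = attr(control, "cell_type", exact = TRUE),
    condition = "disease",
    params = list(perturbed = out$picked, seed = seed)
  )
  list(network = disease, perturbed = out$picked)
}

#' Simulate a complete study fixture
#'
#' Convenience wrapper running [simulate_reference()],
#' [simulate_counts()] and [simulate_gold_standard()] under one seed.
#'
#' @inheritParams simulate_reference
#' @return A list with `reference`, `modules`, `gold`, `counts`,
#'   `annotation`, and `config`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  ref <- simulate_reference(cfg, seed = seed)
  cnt <- simulate_counts(cfg, ref$modules, seed = seed + 1L)
  list(
    reference = ref$network,
    modules = ref$modules,
    gold = simulate_gold_standard(ref$modules),
    counts = cnt$counts,
    annotation = cnt$annotation,
    config = cfg
  )
}
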