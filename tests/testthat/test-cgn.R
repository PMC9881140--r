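make_activity <- function(genes, ...) {
  cols <- list(...)
  out <- tibble::tibble(gene = genes)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  structure(out,
            strata = tibble::tibble(label = names(cols),
                                    cell_type = names(cols),
                                    condition = NA_character_),
            class = c("activity_matrix", class(out)))
}

test_that("only reference edges with both endpoints above the cutoff survive", {
  ref <- as_gene_network(tibble::tibble(
    gene_a = c("A", "A", "C"),
    gene_b = c("B", "C", "D"),
    weight = c(1.5, 2.0, 2.5)
  ))
  act <- make_activity(c("A", "B", "C", "D", "E"),
                       t = c(0.9, 0.8, 0.7, -1, 0.95))
  net <- build_cgn(act, ref, "t", threshold_mode = "absolute", threshold = 0)
  # D fails the cutoff: C-D excluded; A-B and A-C retained with ref weights
  expect_equal(nrow(net), 2L)
  expect_equal(net$weight, c(1.5, 2.0))
  # E passes the threshold but has no reference edge: tracked as a node only
  # in the reference-restricted node set
  expect_false("E" %in% network_nodes(net))
  expect_false("D" %in% network_nodes(net))
})

test_that("a pair absent from the reference is never an edge", {
  ref <- as_gene_network(tibble::tibble(gene_a = "A", gene_b = "B", weight = 1))
  act <- make_activity(c("A", "B", "C"), t = c(1, 1, 1))
  net <- build_cgn(act, ref, "t", threshold_mode = "absolute", threshold = 0)
  expect_equal(nrow(net), 1L)  # B-C, A-C pass the threshold but are not edges
})

test_that("retaining all genes gives the induced reference subgraph", {
  ref <- random_network(30, p = 0.2, seed = 8)
  measured <- network_nodes(ref)[1:20]
  act <- make_activity(measured, t = rep(1, 20))
  net <- build_cgn(act, ref, "t", threshold_mode = "absolute", threshold = -10)
  # oracle: brute-force filter of the reference edge table
  oracle <- tibble::as_tibble(ref)
  oracle <- oracle[oracle$gene_a %in% measured & oracle$gene_b %in% measured, ]
  expect_equal(nrow(net), nrow(oracle))
  expect_equal(net$weight, oracle$weight)
})

test_that("every CGN edge and weight exists in the reference", {
  for (seed in 1:5) {
    ref <- random_network(40, p = 0.15, seed = seed)
    genes <- network_nodes(ref)
    act <- make_activity(genes, t = withr::with_seed(seed * 7, rnorm(40)))
    net <- build_cgn(act, ref, "t", threshold = 0.5)
    ref_keys <- paste(ref$gene_a, ref$gene_b)
    net_keys <- paste(net$gene_a, net$gene_b)
    expect_true(all(net_keys %in% ref_keys))
    expect_equal(net$weight, ref$weight[match(net_keys, ref_keys)])
  }
})

test_that("stricter thresholds never add edges", {
  ref <- random_network(40, p = 0.2, seed = 2)
  act <- make_activity(network_nodes(ref), t = withr::with_seed(9, rnorm(40)))
  fractions <- c(0.8, 0.6, 0.4, 0.2, 0.1)
  nets <- lapply(fractions, function(f) build_cgn(act, ref, "t", threshold = f))
  for (i in seq_along(nets)[-1]) {
    looser <- paste(nets[[i - 1]]$gene_a, nets[[i - 1]]$gene_b)
    stricter <- paste(nets[[i]]$gene_a, nets[[i]]$gene_b)
    expect_true(all(stricter %in% looser))
  }
})

test_that("an empty pass-set warns and returns an empty network", {
  ref <- as_gene_network(tibble::tibble(gene_a = "A", gene_b = "B", weight = 1))
  act <- make_activity(c("A", "B"), t = c(-1, -1))
  expect_warning(
    net <- build_cgn(act, ref, "t", threshold_mode = "absolute", threshold = 5),
    "empty pass-set"
  )
  expect_equal(nrow(net), 0L)
  expect_length(network_nodes(net), 0L)
})

test_that("build_all_cgns makes one network per stratum and writes files", {
  cfg <- small_sim_config()
  st <- simulate_study(cfg, seed = 21)
  annot <- st$annotation
  annot$condition <- rep(c("ctrl", "case"), length.out = nrow(annot))
  out_dir <- withr::local_tempdir()
  nets <- build_all_cgns(st$counts, annot, st$reference,
                         min_cells = 10, out_dir = out_dir)
  expect_length(nets, 4L)  # 2 cell types x 2 conditions
  smry <- summary(nets)
  expect_equal(nrow(smry), 4L)
  expect_setequal(smry$status, "built")
  expect_setequal(
    list.files(out_dir),
    c(paste0(smry$label, ".cgn.tsv"), "summary.tsv")
  )
  # written networks load back identically
  lb <- smry$label[1]
  back <- read_network(file.path(out_dir, paste0(lb, ".cgn.tsv")))
  expect_equal(tidy(back), tidy(nets[[lb]]))
  expect_equal(network_nodes(back), network_nodes(nets[[lb]]))
})

test_that("strata below min_cells are reported as skipped, not fatal", {
  cfg <- small_sim_config()
  st <- simulate_study(cfg, seed = 22)
  annot <- st$annotation
  annot$cell_type[1:5] <- "rare"
  annot <- annot[c(which(annot$cell_type == "rare"),
                   which(annot$cell_type != "rare")), ]
  expect_warning(
    nets <- build_all_cgns(st$counts, annot, st$reference, min_cells = 20),
    "rare"
  )
  smry <- summary(nets)
  expect_true("skipped: below min_cells" %in% smry$status)
  expect_false("rare" %in% names(nets))
})

test_that("planted-module genes are enriched in their cell type's pass-set", {
  cfg <- sim_config(n_genes = 100L, n_modules = 4L, module_size = 15L,
                    p_within = 0.5, p_background = 0.03,
                    cell_types = c(alpha = 80L, beta = 80L))
  pvals <- vapply(1:10, function(seed) {
    st <- simulate_study(cfg, seed = 100 + seed)
    act <- compute_activity(st$counts, st$annotation, min_cells = 10)
    net <- build_cgn(act, st$reference, "alpha", threshold = 0.5)
    planted <- st$modules$gene[!is.na(st$modules$module) &
                                 st$modules$module == "M1"]
    others <- st$modules$gene[!is.na(st$modules$module) &
                                st$modules$module != "M1"]
    pass <- network_nodes(net)
    tab <- matrix(c(sum(planted %in% pass), sum(!planted %in% pass),
                    sum(others %in% pass), sum(!others %in% pass)),
                  nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})
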