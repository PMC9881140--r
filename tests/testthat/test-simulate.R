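test_that("degenerate edge probabilities give closed-form graphs", {
  cfg <- sim_config(n_genes = 20, n_modules = 4, module_size = 5,
                    p_within = 1, p_background = 0)
  ref <- simulate_reference(cfg, seed = 1)
  expect_equal(nrow(ref$network), 4 * choose(5, 2))
  # disjoint cliques: every edge is within one module
  mod <- setNames(ref$modules$module, ref$modules$gene)
  expect_true(all(mod[ref$network$gene_a] == mod[ref$network$gene_b]))

  cfg0 <- sim_config(n_genes = 10, n_modules = 5, module_size = 1,
                     p_within = 1, p_background = 0)
  ref0 <- simulate_reference(cfg0, seed = 1)
  expect_equal(nrow(ref0$network), 0L)
})

test_that("edge counts match the binomial expectation across seeds", {
  cfg <- sim_config(n_genes = 100, n_modules = 4, module_size = 10,
                    p_within = 0.4, p_background = 0.02)
  n_within_pairs <- 4 * choose(10, 2)
  n_bg_pairs <- choose(100, 2) - n_within_pairs
  expected <- n_within_pairs * 0.4 + n_bg_pairs * 0.02
  sd_count <- sqrt(n_within_pairs * 0.4 * 0.6 + n_bg_pairs * 0.02 * 0.98)
  counts <- vapply(1:20, function(s) nrow(simulate_reference(cfg, s)$network),
                   numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sd_count / sqrt(20))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_sim_config()
  a <- simulate_study(cfg, seed = 5)
  b <- simulate_study(cfg, seed = 5)
  expect_identical(tibble::as_tibble(a$reference), tibble::as_tibble(b$reference))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$annotation, b$annotation)
  c <- simulate_study(cfg, seed = 6)
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
})

test_that("planted genes reach effect x baseline mean in their cell type", {
  cfg <- sim_config(n_genes = 100, n_modules = 2, module_size = 25,
                    p_within = 0.3, p_background = 0.01,
                    cell_types = c(alpha = 300L, beta = 300L),
                    expression_effect = 4, dropout_prob = 0.5,
                    nb_dispersion = 0.5)
  ref <- simulate_reference(cfg, seed = 2)
  cnt <- simulate_counts(cfg, ref$modules, seed = 3)
  m <- as.matrix(cnt$counts)
  alpha_cells <- cnt$annotation$cell_id[cnt$annotation$cell_type == "alpha"]
  m1 <- ref$modules$gene[!is.na(ref$modules$module) & ref$modules$module == "M1"]

  # with dropout q and boost f, E[count] = (1 - q) * f * mu_g; compare the
  # planted genes' empirical means pooled over genes and cells against the
  # same genes in the non-planted cell type, where the boost is absent
  beta_cells <- setdiff(cnt$annotation$cell_id, alpha_cells)
  ratio <- mean(m[m1, alpha_cells]) / mean(m[m1, beta_cells])
  # NB + dropout variance of the pooled mean is tiny at 25 genes x 300 cells
  expect_lt(abs(ratio - 4), 0.4)
})

test_that("extreme dropout and null effect behave as expected", {
  cfg <- sim_config(n_genes = 30, n_modules = 2, module_size = 5,
                    cell_types = c(a = 30L, b = 30L), dropout_prob = 1)
  ref <- simulate_reference(cfg, seed = 1)
  cnt <- simulate_counts(cfg, ref$modules, seed = 2)
  expect_true(all(as.matrix(cnt$counts) == 0))

  cfg1 <- sim_config(n_genes = 40, n_modules = 2, module_size = 10,
                     cell_types = c(a = 200L, b = 200L),
                     expression_effect = 1, dropout_prob = 0.3)
  ref1 <- simulate_reference(cfg1, seed = 3)
  cnt1 <- simulate_counts(cfg1, ref1$modules, seed = 4)
  m <- as.matrix(cnt1$counts)
  ann <- cnt1$annotation
  mean_a <- mean(m[, ann$cell_type == "a"])
  mean_b <- mean(m[, ann$cell_type == "b"])
  # no cell type differs when the effect is 1
  expect_lt(abs(mean_a - mean_b) / mean_a, 0.1)
})

test_that("module_size 1 leaves the gold standard undefined", {
  mods <- tibble::tibble(gene = c("A", "B", "C"),
                         module = c("M1", "M2", NA))
  expect_error(simulate_gold_standard(mods), "undefined")
})

test_that("the LLS curve of a module-aware ranking starts positive", {
  st <- simulate_study(small_sim_config(), seed = 31)
  mod <- setNames(st$modules$module, st$modules$gene)
  links <- tibble::as_tibble(st$reference)[, c("gene_a", "gene_b")]
  same <- !is.na(mod[links$gene_a]) & !is.na(mod[links$gene_b]) &
    mod[links$gene_a] == mod[links$gene_b]
  links$score <- ifelse(same, 2, 1) + withr::with_seed(32, runif(nrow(links)) / 10)
  curve <- lls_curve(links, st$gold, bin_size = 50)
  expect_gt(curve$lls[1], 0)
})

test_that("the planted disease module sits on top of the control network", {
  st <- simulate_study(small_sim_config(), seed = 41)
  act <- compute_activity(st$counts, st$annotation, min_cells = 10)
  control <- build_cgn(act, st$reference, "alpha")
  dz <- simulate_disease_network(control, reference = st$reference, seed = 42)
  expect_length(dz$perturbed, 8L)
  expect_true(all(!dz$perturbed %in% network_nodes(control)))
  # control edges are untouched
  ctrl_keys <- paste(control$gene_a, control$gene_b)
  dz_keys <- paste(dz$network$gene_a, dz$network$gene_b)
  expect_true(all(ctrl_keys %in% dz_keys))
  expect_equal(nrow(dz$network), nrow(control) + choose(8, 2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, n_modules = 3, module_size = 5),
               "must not exceed")
  expect_error(sim_config(p_within = 1.5), "p_within")
  expect_error(sim_config(expression_effect = 0.5), "expression_effect")
})
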