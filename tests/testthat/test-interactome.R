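test_that("edge lists are deduplicated, self-loops dropped, bad rows rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t1.5", "B\tA\t1.5", "A\tA\t2.0"), path)
  expect_warning(net <- load_interactome(path), "self-loop")
  expect_equal(nrow(net), 1L)
  expect_equal(net$gene_a, "A")
  expect_equal(net$gene_b, "B")
  expect_equal(net$weight, 1.5)

  writeLines(c("A\tB\t1.5", "B\tC\tnot_a_number"), path)
  expect_error(load_interactome(path), "line 2")

  writeLines(c("A\tB\t1.5", "B\tC\t-2"), path)
  expect_error(load_interactome(path), "onpositive")

  writeLines(c("A\tB"), path)
  expect_error(load_interactome(path), "default_weight")
  expect_equal(load_interactome(path, default_weight = 2)$weight, 2)
})

test_that("header auto-detection and coding-gene filtering work", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tweight", "A\tB\t1", "B\tC\t2", "C\tD\t3"), path)
  net <- load_interactome(path)
  expect_equal(nrow(net), 3L)
  expect_message(
    net2 <- load_interactome(path, coding_genes = c("A", "B", "C")),
    "non-coding"
  )
  expect_equal(nrow(net2), 2L)
  expect_false("D" %in% network_nodes(net2))
})

test_that("networks round-trip through write_network/read_network unchanged", {
  net <- random_network(10, p = 0.35, seed = 42)
  expect_gte(nrow(net), 10)  # comfortably above the 15-edge scale at p = 0.35
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(tidy(back), tidy(net))
  expect_equal(network_nodes(back), network_nodes(net))

  # and through load_interactome, which ignores the node header
  loaded <- load_interactome(path)
  expect_equal(tidy(loaded), tidy(net))
})

test_that("gold standard priors follow the pair combinatorics", {
  mods <- tibble::tibble(
    gene = sprintf("G%02d", 1:10),
    module = c(rep("M1", 4), rep("M2", 4), NA, NA)
  )
  gs <- simulate_gold_standard(mods)
  expect_equal(length(gs$positives), 12L)  # 2 * choose(4, 2)
  expect_equal(gs$p_l, 12 / 45)
  expect_error(
    gold_standard(data.frame(a = character(), b = character()), c("A", "B")),
    "P\\(L\\)"
  )
  expect_error(
    gold_standard(data.frame(a = "X", b = "Y"), c("A", "B", "X")),
    "outside the universe"
  )
})

test_that("binned LLS matches direct evaluation of the formula", {
  # 10 genes, 10 positives -> prior odds 10/35; one bin of 5 links, 3 positive
  genes <- sprintf("G%02d", 1:10)
  pos <- data.frame(
    a = c("G01", "G01", "G02", "G03", "G04", "G05", "G06", "G07", "G08", "G09"),
    b = c("G02", "G03", "G03", "G04", "G05", "G06", "G07", "G08", "G09", "G10")
  )
  gs <- gold_standard(pos, genes)
  expect_equal(gs$prior_odds, (10 / 45) / (35 / 45))
  links <- data.frame(
    a = c("G01", "G02", "G04", "G01", "G02"),
    b = c("G02", "G03", "G05", "G05", "G06"),
    score = 5:1
  )
  curve <- lls_curve(links, gs, bin_size = 5)
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$n_pos, 3L)
  expect_equal(curve$lls, log((3 / 2) / (10 / 35)))
})

test_that("a bin whose odds equal the prior odds scores exactly zero", {
  # universe of 6 genes, 5 positives out of 15 pairs: prior odds 5/10 = 1/2
  genes <- sprintf("G%d", 1:6)
  all_pairs <- t(utils::combn(genes, 2))
  gs <- gold_standard(data.frame(all_pairs[1:5, ]), genes)
  # one bin with 1 positive and 2 negatives reproduces odds 1/2
  links <- data.frame(
    a = c(all_pairs[1, 1], all_pairs[8, 1], all_pairs[12, 1]),
    b = c(all_pairs[1, 2], all_pairs[8, 2], all_pairs[12, 2]),
    score = 3:1
  )
  curve <- lls_curve(links, gs, bin_size = 3)
  expect_equal(curve$lls, 0)
})

test_that("ranking the positives first gives a flagged all-positive bin", {
  genes <- sprintf("G%d", 1:5)
  pairs <- t(utils::combn(genes, 2))  # 10 pairs
  gs <- gold_standard(data.frame(pairs[1:5, ]), genes)  # P(L) = 0.5
  links <- data.frame(a = pairs[, 1], b = pairs[, 2], score = 10:1)
  curve <- lls_curve(links, gs, bin_size = 5)
  expect_true(curve$degenerate[1])   # 5 positives, 0 negatives -> +Inf
  expect_equal(curve$lls[1], Inf)
  expect_true(curve$degenerate[2])   # 0 positives -> -Inf
  expect_equal(curve$lls[2], -Inf)
})

test_that("links outside the gold universe are skipped, not counted negative", {
  genes <- c("A", "B", "C", "D")
  gs <- gold_standard(data.frame(a = "A", b = "B"), genes)
  links <- data.frame(
    a = c("A", "X", "C"), b = c("B", "Y", "D"), score = 3:1
  )
  curve <- lls_curve(links, gs, bin_size = 10)
  expect_equal(curve$n_links, 2L)  # X-Y dropped entirely
  expect_equal(curve$n_pos, 1L)
  expect_equal(curve$n_neg, 1L)
})

test_that("positives-first orderings give non-increasing bin LLS", {
  for (seed in 1:5) {
    net <- withr::with_seed(seed, {
      genes <- sprintf("G%02d", 1:20)
      pairs <- t(utils::combn(genes, 2))
      idx <- sample(nrow(pairs), 80)
      gs <- gold_standard(data.frame(pairs[idx[1:30], ]), genes)
      ranked <- data.frame(pairs[idx, ], score = length(idx):1)
      list(gs = gs, ranked = ranked)
    })
    curve <- lls_curve(net$ranked, net$gs, bin_size = 20)
    n <- nrow(curve)
    expect_true(all(curve$lls[-1] <= curve$lls[-n] + 1e-12))
  }
})

test_that("random rankings score near zero on average", {
  genes <- sprintf("G%02d", 1:40)
  pairs <- t(utils::combn(genes, 2))  # 780
  gs <- withr::with_seed(7, gold_standard(data.frame(pairs[sample(780, 200), ]), genes))
  means <- vapply(1:60, function(seed) {
    links <- withr::with_seed(seed + 100, {
      idx <- sample(nrow(pairs), 400)
      data.frame(pairs[idx, ], score = stats::runif(400))
    })
    curve <- lls_curve(links, gs, bin_size = 100)
    mean(curve$lls[is.finite(curve$lls)])
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.1)
})
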