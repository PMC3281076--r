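test_that("one-sided Fisher matches full-table enumeration", {
  expect_equal(fisher_one_sided(0, 20, 0, 20), 1)
  expect_equal(fisher_one_sided(2, 1, 1, 2), 0.5, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0) next
    expect_equal(fisher_one_sided(a, b, c_, d),
                 enum_fisher_greater(a, b, c_, d), tolerance = 1e-12)
  }
  expect_error(fisher_one_sided(-1, 2, 3, 4), "nonnegative")
})

test_that("binomial tail matches direct log-space summation", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(5, 5, 0.5), 0.03125)
  expect_equal(binomial_tail(5, 10, 0.2), sum_binom_tail(5, 10, 0.2),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:50, 1); k <- sample(0:n, 1); p0 <- runif(1)
    expect_equal(binomial_tail(k, n, p0), sum_binom_tail(k, n, p0),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail(2, 5, 1.5), "p0")
})

test_that("term enrichment ranks a perfectly matching category first", {
  universe <- sprintf("g%03d", 1:100)
  gene_set <- universe[1:10]
  cats <- list(exact = gene_set,
               disjoint = universe[51:60],
               broad = universe[1:50])
  res <- term_enrichment(gene_set, cats, universe)
  expect_equal(res$category_id[1], "exact")
  expect_equal(res$overlap[res$category_id == "disjoint"], 0)
  expect_equal(res$percent_overlap[res$category_id == "exact"], 1)
  # overlap 0 means P(X >= 0) = 1
  expect_equal(res$p_value[res$category_id == "disjoint"], 1)
  # oracle for the broad category: P(overlap >= 10) drawing 10 from 100
  p_broad <- sum(dhyper(10, 50, 50, 10))
  expect_equal(res$p_value[res$category_id == "broad"], p_broad,
               tolerance = 1e-12)
  # invariant to renaming gene ids
  ren <- setNames(sprintf("x%03d", 1:100), universe)
  res2 <- term_enrichment(unname(ren[gene_set]),
                          lapply(cats, function(g) unname(ren[g])),
                          unname(ren[universe]))
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_error(term_enrichment(gene_set, cats, character(0)), "universe")
  expect_error(term_enrichment("nope", cats, universe), "universe")
})

down_sim <- function(seed, enrich_targets = FALSE) {
  n_genes <- 240
  d <- simulation_design(n_cases = 8, n_controls = 8, n_features = n_genes,
                         n_de = 30, de_direction = "down",
                         log2_fc_range = c(2, 3), corr_blocks = list(),
                         seed = seed)
  sim <- simulate_feature_matrix(d)
  genes <- sprintf("g%03d", seq_len(n_genes))
  rownames(sim$matrix) <- genes
  down_genes <- genes[sim$truth$is_de]
  null_genes <- genes[!sim$truth$is_de]
  tgt <- if (enrich_targets) {
    # targets 3x enriched for planted down-regulation
    c(sample(down_genes, 18), sample(null_genes, 42))
  } else {
    sample(genes, 60)
  }
  list(sim = sim, targets = list("mir-0001" = tgt))
}

test_that("target down-regulation test has power where it should", {
  set.seed(41)
  s <- down_sim(seed = 101, enrich_targets = TRUE)
  res <- target_downregulation_test(s$sim$matrix, s$sim$meta$group,
                                    s$targets, "mir-0001",
                                    n_permutations = 150, sam_seed = 1)
  expect_lt(res$p_fisher, 0.05)
  expect_lt(res$p_binomial, 0.05)
  expect_equal(sum(res$counts), 240)
  expect_equal(res$counts["target", "down"] + res$counts["target", "not_down"],
               60)
})

test_that("random targets do not trigger the down-regulation test", {
  set.seed(42)
  ps <- vapply(1:8, function(i) {
    s <- down_sim(seed = 200 + i)
    target_downregulation_test(s$sim$matrix, s$sim$meta$group, s$targets,
                               "mir-0001", n_permutations = 120,
                               sam_seed = i)$p_fisher
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 2)
})

test_that("degenerate target maps are rejected", {
  s <- down_sim(seed = 300)
  all_targets <- list("mir-0001" = rownames(s$sim$matrix))
  expect_error(
    target_downregulation_test(s$sim$matrix, s$sim$meta$group, all_targets,
                               "mir-0001", n_permutations = 60),
    "non-target")
  expect_warning(
    target_downregulation_test(s$sim$matrix, s$sim$meta$group, s$targets,
                               c("mir-0001", "mir-ghost"),
                               n_permutations = 60, sam_seed = 2),
    "mir-ghost")
})
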