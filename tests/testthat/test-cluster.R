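test_that("sample clustering is complete-linkage on Euclidean distance", {
  meta <- toy_meta(3, 3)
  m <- toy_matrix(meta, 10, seed = 2)
  m[, "p02"] <- m[, "p01"]  # duplicated sample
  hs <- hier_cluster_samples(m, meta)
  expect_s3_class(hs$hclust, "hclust")
  # zero-distance pair merges first, heights never decrease
  expect_equal(hs$hclust$height[1], 0)
  expect_true(!is.unsorted(hs$hclust$height))
  expect_error(hier_cluster_samples(m[, 1, drop = FALSE]), "at least 2")
})

test_that("well-separated groups are recovered by the two-group cut", {
  d <- simulation_design(n_cases = 6, n_controls = 6, n_features = 40,
                         n_de = 20, log2_fc_range = c(4, 4),
                         noise_sd_range = c(0.3, 0.3),
                         corr_blocks = list(), seed = 12)
  sim <- simulate_feature_matrix(d)
  hs <- hier_cluster_samples(sim$matrix, sim$meta)
  expect_equal(hs$misclassified, 0)
})

test_that("correlation matrix matches a brute-force pairwise oracle", {
  meta <- toy_meta(20, 20)
  m <- toy_matrix(meta, 10, seed = 9)
  cc <- correlation_clusters(m, r_threshold = 0.6)
  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- cor(m[i, ], m[j, ])
  dimnames(oracle) <- list(rownames(m), rownames(m))
  expect_equal(cc$correlation_matrix, oracle, tolerance = 1e-10)
  expect_equal(unname(diag(cc$correlation_matrix)), rep(1, 10))
})

test_that("pairwise p-values match numerical integration of the t density", {
  p_impl <- circumir:::pearson_p(0.6, 40)
  p_oracle <- 2 * integrate(function(x) dt(x, 38),
                            0.6 * sqrt(38) / sqrt(1 - 0.36), Inf,
                            rel.tol = 1e-12)$value
  expect_equal(p_impl, p_oracle, tolerance = 1e-8)
  expect_gt(p_impl, 1e-5)
  expect_lt(p_impl, 1e-4)
})

test_that("duplicated features land in one cluster; noise makes none", {
  meta <- toy_meta(20, 20)
  m <- toy_matrix(meta, 8, seed = 4)
  m[2, ] <- m[1, ]  # exact duplicate, r = 1
  cc <- correlation_clusters(m, r_threshold = 0.6)
  inc <- vapply(cc$clusters, function(cl)
    all(rownames(m)[1:2] %in% cl), logical(1))
  expect_true(any(inc))
  # independent noise: clusters of size >= 2 are rare at threshold 0.6
  none <- vapply(1:20, function(i) {
    mm <- toy_matrix(meta, 10, seed = 100 + i)
    length(correlation_clusters(mm, r_threshold = 0.6)$clusters) == 0
  }, logical(1))
  expect_gte(sum(none), 17)
})

test_that("zero-variance features are set aside with a warning", {
  meta <- toy_meta(4, 4)
  m <- toy_matrix(meta, 5, seed = 6)
  m[3, ] <- 7
  expect_warning(cc <- correlation_clusters(m, r_threshold = 0.5),
                 "zero-variance")
  expect_true(rownames(m)[3] %in% cc$unassigned)
})

test_that("planted correlation blocks are extracted", {
  d <- simulation_design(n_features = 34, n_de = 0,
                         corr_blocks = list(c(10, 0.75), c(8, 0.75),
                                            c(6, 0.75), c(4, 0.75)),
                         seed = 23)
  sim <- simulate_feature_matrix(d)
  cc <- correlation_clusters(sim$matrix, r_threshold = 0.6)
  truth_lab <- ifelse(is.na(sim$truth$block),
                      paste0("s", seq_len(nrow(sim$truth))),
                      paste0("b", sim$truth$block))
  found <- setNames(paste0("s", seq_len(nrow(sim$truth))),
                    sim$truth$feature_id)
  for (i in seq_along(cc$clusters)) found[cc$clusters[[i]]] <- paste0("c", i)
  expect_gt(ari(truth_lab, found[sim$truth$feature_id]), 0.8)
  expect_true(all(cc$summary$min_pairwise_r > 0.6))
})

test_that("co-localization pairs loci within the gap on one chromosome", {
  loci <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(100, 500, 100, 100),
    end   = c(200, 600, 200, 200),
    stringsAsFactors = FALSE)
  out <- colocalize(loci, max_gap_bp = 1000)
  # identical loci a and d overlap: gap 0; a/b and b/d gap 300; c alone
  expect_equal(out$gap_bp[out$feature_a == "a" & out$feature_b == "d"], 0)
  expect_equal(out$gap_bp[out$feature_a == "a" & out$feature_b == "b"], 300)
  expect_false("c" %in% c(out$feature_a, out$feature_b))
  expect_equal(nrow(colocalize(loci, max_gap_bp = 100)), 1)  # only the overlap
})
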