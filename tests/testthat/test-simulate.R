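test_that("simulation is deterministic in the seed and matches its truth table", {
  d <- simulation_design(n_features = 60, n_de = 5, seed = 5,
                         corr_blocks = list(c(4, 0.5)))
  a <- simulate_feature_matrix(d)
  b <- simulate_feature_matrix(d)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  # null features carry planted fold change exactly 1
  expect_true(all(a$truth$fold_change[!a$truth$is_de] == 1))
  expect_equal(sum(a$truth$is_de), 5)
  pa <- simulate_probe_matrix(d)
  pb <- simulate_probe_matrix(d)
  expect_identical(pa$probes, pb$probes)
})

test_that("null design has symmetric group differences", {
  d <- simulation_design(n_features = 400, n_de = 0, corr_blocks = list(),
                         seed = 9)
  sim <- simulate_feature_matrix(d)
  is_case <- sim$meta$group == "case"
  diffs <- rowMeans(sim$matrix[, is_case]) - rowMeans(sim$matrix[, !is_case])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("planted fold changes are recovered on average", {
  d <- simulation_design(n_features = 300, n_de = 30,
                         log2_fc_range = c(1, 1), noise_sd_range = c(0.5, 0.5),
                         corr_blocks = list(), seed = 13)
  sim <- simulate_feature_matrix(d)
  is_case <- sim$meta$group == "case"
  diffs <- rowMeans(sim$matrix[, is_case]) - rowMeans(sim$matrix[, !is_case])
  de <- sim$truth$is_de
  # mean observed shift over the 30 planted features: se = 0.5*sqrt(2/20)/sqrt(30)
  expect_lt(abs(mean(diffs[de]) - 1), 3 * 0.5 * sqrt(2 / 20) / sqrt(30))
})

test_that("latent blocks reach their target pairwise correlation", {
  rho <- 0.75
  rs <- replicate(50, {
    d <- simulation_design(n_features = 10, n_de = 0,
                           corr_blocks = list(c(5, rho)),
                           seed = sample.int(1e6, 1))
    sim <- simulate_feature_matrix(d)
    cm <- cor(t(sim$matrix[1:5, ]))
    mean(cm[upper.tri(cm)])
  })
  expect_lt(abs(mean(rs) - rho), 0.1)
  # features outside blocks stay uncorrelated on average
  d <- simulation_design(n_features = 40, n_de = 0, corr_blocks = list(),
                         seed = 2)
  sim <- simulate_feature_matrix(d)
  cm <- cor(t(sim$matrix))
  expect_lt(abs(mean(cm[upper.tri(cm)])), 0.05)
})

test_that("noise-free probe construction is exactly invertible", {
  # constant columns (no DE, no noise, no blocks) keep quantile
  # normalization a no-op, so the chain must invert the construction
  d <- simulation_design(n_cases = 3, n_controls = 3, n_features = 20,
                         n_de = 0, noise_sd_range = c(0, 0),
                         corr_blocks = list(), probes_per_feature = 3,
                         seed = 4)
  sim <- simulate_probe_matrix(d, background_per_gc = 0, affinity_sd = 0,
                               probe_noise_sd = 0)
  pp <- preprocess_probes(sim$probes, sim$meta)
  expect_equal(pp$matrix[rownames(sim$feature), colnames(sim$feature)],
               log2(2^sim$feature + 16), tolerance = 1e-12)
})

test_that("planted GC background is removed by correction", {
  d <- simulation_design(n_cases = 3, n_controls = 3, n_features = 30,
                         n_de = 0, corr_blocks = list(),
                         probes_per_feature = 2, seed = 6)
  bg_fun <- function(gc) ifelse(gc == 10, 500, 0)  # one loaded GC class
  sim <- simulate_probe_matrix(d, background_per_gc = bg_fun,
                               affinity_sd = 0, probe_noise_sd = 0)
  corrected <- gc_background_correct(sim$probes)
  clean <- simulate_probe_matrix(d, background_per_gc = 0, affinity_sd = 0,
                                 probe_noise_sd = 0)
  clean_gx <- clean$probes[!clean$probes$is_antigenomic, ]
  sam_cols <- setdiff(names(corrected),
                      c("probe_id", "feature_id", "gc_count",
                        "is_antigenomic"))
  expect_equal(as.matrix(corrected[sam_cols]),
               as.matrix(clean_gx[sam_cols]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("target map simulation matches its combinatorial expectations", {
  tm <- simulate_target_map(4, 10, 10, seed = 3)
  expect_true(all(lengths(tm) == 10))       # everything targeted
  tm0 <- simulate_target_map(4, 10, 0, seed = 3)
  expect_true(all(lengths(tm0) == 0))
  # expected pairwise overlap ~ t^2 / n_genes
  tm2 <- simulate_target_map(40, 200, 30, seed = 8)
  prs <- combn(names(tm2), 2)
  ov <- vapply(seq_len(ncol(prs)), function(k)
    length(intersect(tm2[[prs[1, k]]], tm2[[prs[2, k]]])), numeric(1))
  expect_lt(abs(mean(ov) - 30^2 / 200), 0.5)
  expect_identical(simulate_target_map(4, 10, 5, seed = 2),
                   simulate_target_map(4, 10, 5, seed = 2))
})
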