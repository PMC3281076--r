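test_that("modified t-scores match the pooled-t oracle and its symmetries", {
  meta <- toy_meta(4, 4)
  m <- matrix(c(10, 11, 10, 11, 8, 9, 8, 9,
                rep(5, 8)), 2, 8, byrow = TRUE,
              dimnames = list(c("f1", "f2"), meta$sample_id))
  labels <- meta$group
  d <- sam_scores(m, labels, s0 = 0)
  # identical case and control values -> zero numerator
  expect_equal(unname(d["f2"]), 0)
  # oracle: classic pooled-variance t statistic equals d at s0 = 0
  tt <- t.test(m["f1", 1:4], m["f1", 5:8], var.equal = TRUE)$statistic
  expect_equal(unname(d["f1"]), unname(tt), tolerance = 1e-12)
  # label swap flips the sign, magnitude unchanged
  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(sam_scores(m, swapped, s0 = 0), -d, tolerance = 1e-12)
  expect_error(sam_scores(m, rep("case", 8)), "at least 2")
})

test_that("fold change is the anti-logged difference of log2 means", {
  meta <- toy_meta(2, 2)
  m <- rbind(equal = c(3, 5, 4, 4),
             up1 = c(5, 5, 4, 4),
             dnhalf = c(4, 4, 4.25, 4.75))
  colnames(m) <- meta$sample_id
  fc <- fold_change(m, meta$group)
  expect_equal(unname(fc), c(1, 2, 2^(-0.5)), tolerance = 1e-12)
})

test_that("s0 tuning behaves at its edges and finds structure", {
  meta <- toy_meta(5, 5)
  # all standard errors zero: constant within groups
  m0 <- matrix(rep(c(1, 2), each = 5), 4, 10, byrow = TRUE,
               dimnames = list(paste0("f", 1:4), meta$sample_id))
  expect_warning(s <- choose_s0(m0, meta$group), "zero")
  expect_equal(s, 1e-8)
  # fixed mode bypasses tuning
  pars <- sam_params(s0_mode = "fixed", s0_value = 0.5)
  expect_equal(pars$s0_value, 0.5)
  expect_error(sam_params(s0_mode = "fixed"), "s0_value")
  # variance strongly increasing with mean pushes s0 above zero
  set.seed(11)
  sds <- seq(0.05, 2, length.out = 200)
  m <- matrix(rnorm(200 * 10, sd = rep(sds, 10)), 200, 10,
              dimnames = list(sprintf("f%03d", 1:200), meta$sample_id))
  expect_gt(choose_s0(m, meta$group), 0)
})

test_that("sam calibration is invariant to sample order (exact null)", {
  meta <- toy_meta(5, 5)
  d <- simulation_design(n_cases = 5, n_controls = 5, n_features = 80,
                         n_de = 4, log2_fc_range = c(2, 2),
                         corr_blocks = list(), seed = 3)
  sim <- simulate_feature_matrix(d)
  pars <- sam_params(n_permutations = 300, seed = 7)  # 252 exact perms
  r1 <- sam_calibrate(sim$matrix, sim$meta$group, pars)
  expect_equal(r1$n_permutations_used, choose(10, 5))
  set.seed(1)
  shuf <- sample(ncol(sim$matrix))
  r2 <- sam_calibrate(sim$matrix[, shuf], sim$meta$group[shuf], pars)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$delta, r2$delta)
})

test_that("called features respect the q-value contract and delta monotonicity", {
  d <- simulation_design(n_features = 200, n_de = 10,
                         log2_fc_range = c(1, 1.5), corr_blocks = list(),
                         seed = 17)
  sim <- simulate_feature_matrix(d)
  loose <- sam_calibrate(sim$matrix, sim$meta$group,
                         sam_params(fdr_target = 0.10,
                                    n_permutations = 150, seed = 5))
  strict <- sam_calibrate(sim$matrix, sim$meta$group,
                          sam_params(fdr_target = 0.01,
                                     n_permutations = 150, seed = 5))
  # q <= target for every called feature, at both targets
  expect_true(all(loose$table$q_value[loose$table$called] <= 0.10 + 1e-12))
  expect_true(all(strict$table$q_value[strict$table$called] <= 0.01 + 1e-12))
  # a stricter FDR raises delta and can only shrink the called set
  expect_gte(strict$delta, loose$delta)
  expect_true(all(strict$table$feature_id[strict$table$called] %in%
                    loose$table$feature_id[loose$table$called]))
  expect_true(sum(strict$table$called) >= 8)  # strong planted signal found
  expect_true(all(strict$table$direction[strict$table$called] == "up"))
})

test_that("pure-null data yields no calls at FDR 1%", {
  calls <- vapply(1:3, function(i) {
    d <- simulation_design(n_features = 300, n_de = 0,
                           corr_blocks = list(), seed = 20 + i)
    sim <- simulate_feature_matrix(d)
    res <- sam_calibrate(sim$matrix, sim$meta$group,
                         sam_params(n_permutations = 150, seed = i),
                         compute_q = FALSE)
    sum(res$table$called)
  }, numeric(1))
  expect_equal(median(calls), 0)
})

test_that("permutation sampling is exact when the space is small", {
  ind <- circumir:::sample_label_perms(6, 3, 1000, seed = 1)
  expect_equal(ncol(ind), choose(6, 3))
  expect_equal(colSums(ind), rep(3, 20))
  expect_equal(anyDuplicated(apply(ind, 2, paste, collapse = "")), 0)
  ind2 <- circumir:::sample_label_perms(30, 15, 50, seed = 9)
  expect_equal(ncol(ind2), 50)
  expect_equal(anyDuplicated(apply(ind2, 2, paste, collapse = "")), 0)
  expect_identical(ind2, circumir:::sample_label_perms(30, 15, 50, seed = 9))
})
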