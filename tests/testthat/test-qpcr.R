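qpcr_table <- function(target_ct, normalizer_ct) {
  # target_ct / normalizer_ct: named list group -> replicate Ct vectors
  rows <- list()
  for (g in names(target_ct)) {
    for (r in seq_along(target_ct[[g]])) {
      rid <- paste0("r", r)
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = "mir-x", group = g, replicate_id = rid,
        ct = target_ct[[g]][r], is_normalizer = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = "norm1", group = g, replicate_id = rid,
        ct = normalizer_ct[[g]][r], is_normalizer = TRUE)
    }
  }
  do.call(rbind, rows)
}

test_that("delta-Ct arithmetic hits its closed forms", {
  # target Ct equals normalizer Ct everywhere: all values 1, fc 1
  q <- qpcr_table(list(case = c(20, 20), control = c(22, 22)),
                  list(case = c(20, 20), control = c(22, 22)))
  r <- delta_ct_fold_change(q, "mir-x")
  expect_equal(unname(c(r$values$case, r$values$control)), rep(1, 4))
  expect_equal(r$fold_change, 1)

  # case deltaCt uniformly one cycle below control: fc = 2 exactly
  q2 <- qpcr_table(list(case = c(19, 21), control = c(20, 22)),
                   list(case = c(20, 22), control = c(20, 22)))
  # replicate values are constant within groups here, so the t-test is
  # degenerate and warns; the fold change is still exact
  expect_warning(r2 <- delta_ct_fold_change(q2, "mir-x"), "zero variance")
  expect_equal(r2$fold_change, 2, tolerance = 1e-12)
})

test_that("a 4v4 toy table matches the hand-computed formula chain", {
  tc <- list(case = c(18.0, 18.4, 18.2, 18.1),
             control = c(19.0, 19.3, 19.1, 19.2))
  nc <- list(case = c(20.0, 20.2, 20.1, 20.0),
             control = c(20.1, 20.0, 20.2, 20.1))
  q <- qpcr_table(tc, nc)
  r <- delta_ct_fold_change(q, "mir-x")
  case_v <- 2^(-(tc$case - nc$case))
  ctrl_v <- 2^(-(tc$control - nc$control))
  expect_equal(r$values$case, case_v, tolerance = 1e-12)
  expect_equal(r$fold_change, mean(case_v) / mean(ctrl_v), tolerance = 1e-12)
  # oracle: pooled t through the explicit formula
  sp <- sqrt(((4 - 1) * var(case_v) + (4 - 1) * var(ctrl_v)) / 6)
  tstat <- (mean(case_v) - mean(ctrl_v)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-10)
})

test_that("normalization cancels per-replicate Ct shifts; swap inverts fc", {
  tc <- list(case = c(18.0, 18.5, 17.9), control = c(19.2, 19.0, 19.4))
  nc <- list(case = c(20.0, 20.3, 19.8), control = c(20.1, 20.0, 20.2))
  q <- qpcr_table(tc, nc)
  r <- delta_ct_fold_change(q, "mir-x")
  # add a constant to every Ct of one replicate: values unchanged
  shift <- q
  bump <- shift$group == "case" & shift$replicate_id == "r2"
  shift$ct[bump] <- shift$ct[bump] + 3
  r2 <- delta_ct_fold_change(shift, "mir-x")
  expect_equal(r2$fold_change, r$fold_change, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)
  # swapping the group labels gives the reciprocal fold change
  swapped <- q
  swapped$group <- ifelse(q$group == "case", "control", "case")
  expect_equal(delta_ct_fold_change(swapped, "mir-x")$fold_change,
               1 / r$fold_change, tolerance = 1e-12)
})

test_that("qPCR validation rejects tables without normalizers", {
  q <- qpcr_table(list(case = c(18, 18.1), control = c(19, 19.1)),
                  list(case = c(20, 20), control = c(20, 20)))
  q <- q[!(q$is_normalizer & q$group == "case" & q$replicate_id == "r1"), ]
  expect_error(validate_qpcr_table(q), "normalizer")
})

test_that("platform concordance is a paired t-test on log2 fold changes", {
  fc <- c(a = 1.4, b = 2.0, c = 1.7)
  expect_equal(platform_concordance(fc, fc)$p_value, 1)
  expect_warning(out <- platform_concordance(fc, fc * 2), "constant")
  expect_lt(out$p_value, 1e-200)
  set.seed(3)
  arr <- 2^rnorm(8); qp <- 2^rnorm(8)
  res <- platform_concordance(arr, qp)
  d <- log2(arr) - log2(qp)
  tstat <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 7), tolerance = 1e-10)
  expect_error(platform_concordance(1.5, 2.0), "length")
})
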