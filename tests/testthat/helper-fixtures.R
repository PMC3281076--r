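# Small in-code fixtures shared across test files.

toy_meta <- function(n_cases = 4, n_controls = 4, fraction = "platelet") {
  data.frame(
    sample_id = c(sprintf("p%02d", seq_len(n_cases)),
                  sprintf("c%02d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    fraction = fraction,
    replicate_of = NA_character_,
    stringsAsFactors = FALSE)
}

toy_matrix <- function(meta, n_features = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * nrow(meta), mean = 8), n_features,
              nrow(meta),
              dimnames = list(sprintf("mir-%04d", seq_len(n_features)),
                              meta$sample_id))
  m
}

# probe table: one genomic probe per row plus anti-genomic background rows
toy_probes <- function(genomic, antigenomic) {
  rbind(genomic, antigenomic)
}

# one-sided Fisher p by explicit enumeration of all tables with the given
# margins (independent of phyper)
enum_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  logw <- vapply(xs, function(x)
    -(lfactorial(x) + lfactorial(r1 - x) + lfactorial(c1 - x) +
        lfactorial(r2 - c1 + x)), numeric(1))
  w <- exp(logw - max(logw))
  sum(w[xs >= a]) / sum(w)
}

# upper binomial tail by direct log-space summation
sum_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  terms <- vapply(k:n, function(x)
    lchoose(n, x) + x * log(p0) + (n - x) * log(1 - p0), numeric(1))
  sum(exp(terms))
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
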