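#' One-sided Fisher's exact test on a 2x2 table
#'
#' Upper hypergeometric tail `P(X >= a)` for the top-left cell of
#' `[[a, b], [c, d]]` under fixed margins (alternative: greater), as used
#' for the cohort demographics contrasts and the target down-regulation
#' test.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return p-value in \[0, 1\].
#' @export
#' @examples
#' fisher_one_sided(8, 12, 0, 20) # ~0.0016
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`.
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials.
#' @param p0 success probability under the null.
#' @return p-value in \[0, 1\].
#' @export
binomial_tail <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, n >= 0)
  if (!is.finite(p0) || p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Anti-correlation test: are biomarker targets enriched among
#' down-regulated mRNAs?
#'
#' Runs SAM on the mRNA matrix (default FDR 0.1%), keeps called genes whose
#' case/control fold change clears `fc_min` (down-regulated means
#' `FC <= 1/fc_min`), tabulates target-of-the-panel versus down-regulated
#' status, and tests whether the proportion of down-regulated genes among
#' targets exceeds the proportion among non-targets — by a one-sided Fisher
#' exact test on the 2x2 table and by an upper binomial tail with `p0` the
#' down-regulated fraction among non-targets.
#'
#' @param mrna_expr log2 mRNA expression matrix (genes x samples).
#' @param mrna_labels per-column class labels.
#' @param targets target map (named list miRNA -> gene ids).
#' @param panel character vector of panel miRNA ids; ids without target
#'   sets are warned about and ignored.
#' @param fdr SAM FDR threshold for differential mRNA expression.
#' @param fc_min fold-change filter (symmetric: up means `FC >= fc_min`,
#'   down means `FC <= 1/fc_min`).
#' @param sam_seed,n_permutations permutation stream controls for the SAM
#'   run.
#' @return list: `counts` (2x2 matrix target x down), `p_binomial`,
#'   `p_fisher`, `n_down_targets`, `n_targets`, `p0`, `sam` (the
#'   `"sam_result"`).
#' @export
target_downregulation_test <- function(mrna_expr, mrna_labels, targets,
                                       panel, fdr = 0.001, fc_min = 2.0,
                                       sam_seed = 1,
                                       n_permutations = 500) {
  validate_expr_matrix(mrna_expr)
  stopifnot(fc_min > 1)
  extra <- setdiff(panel, names(targets))
  if (length(extra))
    warning("panel miRNA(s) without target sets: ",
            paste(extra, collapse = ", "))
  tgt_genes <- unique(unlist(targets[intersect(panel, names(targets))]))
  genes <- rownames(mrna_expr)
  is_target <- genes %in% tgt_genes
  if (all(is_target)) stop("no non-target genes: background undefined")

  res <- sam_calibrate(mrna_expr, mrna_labels,
                       sam_params(fdr_target = fdr,
                                  n_permutations = n_permutations,
                                  seed = sam_seed))
  tab <- res$table[match(genes, res$table$feature_id), ]
  is_down <- tab$called & tab$fold_change <= 1 / fc_min

  a <- sum(is_target & is_down)
  b <- sum(is_target & !is_down)
  c_ <- sum(!is_target & is_down)
  d <- sum(!is_target & !is_down)
  p0 <- c_ / (c_ + d)
  counts <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                   dimnames = list(c("target", "non_target"),
                                   c("down", "not_down")))
  list(counts = counts,
       p_fisher = fisher_one_sided(a, b, c_, d),
       p_binomial = binomial_tail(a, a + b, p0),
       n_down_targets = a, n_targets = a + b, p0 = p0, sam = res)
}

#' Hypergeometric term enrichment of a gene set
#'
#' Per category: overlap with the gene set, percent overlap relative to the
#' category size (within the universe), and the one-sided hypergeometric
#' tail p for drawing at least that overlap when sampling `|gene_set|`
#' genes from the universe. Categories are trimmed to the universe first.
#' Results are sorted ascending by p with a Benjamini-Hochberg adjusted
#' column (reported, not used for filtering).
#'
#' @param gene_set character vector (must lie within `universe`).
#' @param categories named list: term -> gene-id vector.
#' @param universe character vector of all testable genes.
#' @return data.frame: category_id, category_size, overlap,
#'   percent_overlap, p_value, p_adjusted.
#' @export
term_enrichment <- function(gene_set, categories, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_set <- unique(gene_set)
  out <- setdiff(gene_set, universe)
  if (length(out)) stop("gene_set not contained in universe: ",
                        paste(utils::head(out, 5), collapse = ", "))
  k <- length(gene_set)
  n_u <- length(universe)
  rows <- lapply(names(categories), function(term) {
    cat_genes <- intersect(unique(categories[[term]]), universe)
    sz <- length(cat_genes)
    ov <- length(intersect(cat_genes, gene_set))
    p <- if (sz == 0) 1 else
      stats::phyper(ov - 1, m = sz, n = n_u - sz, k = k, lower.tail = FALSE)
    data.frame(category_id = term, category_size = sz, overlap = ov,
               percent_overlap = if (sz > 0) ov / sz else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$category_id), , drop = FALSE]
}
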