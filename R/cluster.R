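#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns on Euclidean distance with
#' complete linkage, cut into two groups. The misclassification count is the
#' number of samples on the wrong side under the best of the two possible
#' assignments of cut groups to class labels.
#'
#' @param m log2 expression matrix (features x samples), typically restricted
#'   to a biomarker panel.
#' @param meta optional sample table; when given, the two-group cut is
#'   compared with the case/control labels.
#' @return list: `hclust` (the merge tree), `cut` (named two-group
#'   membership), `misclassified` (count, or `NA` without metadata),
#'   `misclassified_ids` (sample ids on the minority side of the best
#'   matching).
#' @export
hier_cluster_samples <- function(m, meta = NULL) {
  validate_expr_matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster")
  hc <- stats::hclust(stats::dist(t(m)), method = "complete")
  cut <- stats::cutree(hc, k = 2)
  mis <- NA_integer_
  mis_ids <- character(0)
  if (!is.null(meta)) {
    meta <- validate_sample_table(meta, require_groups = FALSE)
    grp <- meta$group[match(names(cut), meta$sample_id)]
    a <- sum((cut == 1) != (grp == "case"))
    b <- sum((cut == 2) != (grp == "case"))
    if (a <= b) {
      mis <- a
      mis_ids <- names(cut)[(cut == 1) != (grp == "case")]
    } else {
      mis <- b
      mis_ids <- names(cut)[(cut == 2) != (grp == "case")]
    }
  }
  list(hclust = hc, cut = cut, misclassified = mis,
       misclassified_ids = mis_ids)
}

# two-sided p for a Pearson r at n samples via the t transform
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Correlation-cluster extraction among selected features
#'
#' Computes the Pearson correlation matrix of the given features over all
#' samples (cases and controls pooled), clusters features hierarchically on
#' distance `1 - r` with complete linkage, cuts the tree at height
#' `1 - r_threshold`, and validates every candidate cluster by iteratively
#' dropping its weakest member (the one with the smallest minimum pairwise r
#' to the rest) until the cluster's minimum pairwise correlation strictly
#' exceeds the threshold. Clusters that shrink below two members dissolve
#' into the unassigned set, as do zero-variance features (whose correlation
#' is undefined). Pairwise two-sided p-values use the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param m log2 expression matrix.
#' @param features feature ids to analyze (must be rows of `m`).
#' @param r_threshold minimum pairwise Pearson correlation a reported
#'   cluster must exceed (default 0.6).
#' @return object of class `"corr_clusters"`: list with
#'   `correlation_matrix`, `clusters` (list of feature-id vectors, largest
#'   first), `summary` (per cluster: size, min/mean pairwise r, max pairwise
#'   p), `unassigned`, `r_threshold`, `n_samples`.
#' @export
correlation_clusters <- function(m, features = rownames(m),
                                 r_threshold = 0.6) {
  validate_expr_matrix(m)
  stopifnot(r_threshold > -1, r_threshold < 1)
  missing <- setdiff(features, rownames(m))
  if (length(missing)) stop("feature(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  if (ncol(m) < 3) stop("need at least 3 samples for correlation analysis")
  x <- m[features, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  unassigned <- rownames(x)[sds == 0]
  if (length(unassigned))
    warning("zero-variance feature(s) moved to unassigned: ",
            paste(unassigned, collapse = ", "))
  x <- x[sds > 0, , drop = FALSE]
  n <- ncol(m)
  cm <- stats::cor(t(x))

  clusters <- list()
  if (nrow(x) >= 2) {
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
    memb <- stats::cutree(hc, h = 1 - r_threshold)
    for (g in unique(memb)) {
      ids <- names(memb)[memb == g]
      # trim until the minimum pairwise r strictly clears the threshold
      while (length(ids) >= 2) {
        sub <- cm[ids, ids, drop = FALSE]
        diag(sub) <- NA
        if (min(sub, na.rm = TRUE) > r_threshold) break
        weakest <- ids[which.min(apply(sub, 1, min, na.rm = TRUE))]
        ids <- setdiff(ids, weakest)
      }
      if (length(ids) >= 2) clusters[[length(clusters) + 1]] <- ids
    }
  }
  assigned <- unlist(clusters)
  unassigned <- union(unassigned, setdiff(rownames(x), assigned))
  if (length(clusters)) {
    clusters <- clusters[order(-lengths(clusters))]
    summary <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      ids <- clusters[[i]]
      sub <- cm[ids, ids]
      rs <- sub[upper.tri(sub)]
      data.frame(cluster = i, size = length(ids),
                 min_pairwise_r = min(rs), mean_pairwise_r = mean(rs),
                 max_pairwise_p = max(pearson_p(rs, n)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    summary <- data.frame(cluster = integer(0), size = integer(0),
                          min_pairwise_r = numeric(0),
                          mean_pairwise_r = numeric(0),
                          max_pairwise_p = numeric(0))
  }
  structure(list(correlation_matrix = cm, clusters = clusters,
                 summary = summary, unassigned = unassigned,
                 r_threshold = r_threshold, n_samples = n),
            class = "corr_clusters")
}

#' @export
print.corr_clusters <- function(x, ...) {
  cat("Correlation clusters (min pairwise r > ", x$r_threshold, "): ",
      length(x$clusters), " cluster(s), ", length(x$unassigned),
      " unassigned feature(s)\n", sep = "")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Genomic co-localization of feature loci
#'
#' Reports every unordered pair of loci on the same chromosome whose
#' interval gap (0 for overlapping or touching intervals; coordinates are
#' 0-based half-open) is at most `max_gap_bp`.
#'
#' @param loci data.frame with feature_id, chrom, start, end (e.g. from
#'   [read_bed_loci()]).
#' @param max_gap_bp maximum gap in base pairs.
#' @return data.frame: feature_a, feature_b, chrom, gap_bp, sorted by gap.
#' @export
colocalize <- function(loci, max_gap_bp) {
  stopifnot(is.data.frame(loci), max_gap_bp >= 0,
            all(c("feature_id", "chrom", "start", "end") %in% names(loci)))
  if (any(loci$start < 0) || any(loci$start >= loci$end))
    stop("loci must satisfy 0 <= start < end")
  out <- list()
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, , drop = FALSE]
    if (nrow(l) < 2) next
    prs <- utils::combn(nrow(l), 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      gap <- max(0, max(l$start[i], l$start[j]) - min(l$end[i], l$end[j]))
      if (gap <= max_gap_bp)
        out[[length(out) + 1]] <- data.frame(
          feature_a = l$feature_id[i], feature_b = l$feature_id[j],
          chrom = ch, gap_bp = gap, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      chrom = character(0), gap_bp = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$gap_bp, res$feature_a), , drop = FALSE]
}
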