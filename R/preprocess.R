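#' Preprocessing parameters
#'
#' @param offset small constant added before the log2 transform (default 16,
#'   the platform QC tool's convention).
#' @param gc_stat statistic of the anti-genomic probes used as the per-GC
#'   background estimate: `"median"` (default) or `"mean"`.
#' @param clamp_floor lower clamp applied after background subtraction.
#' @return list of class `"preprocess_params"`.
#' @export
preprocess_params <- function(offset = 16, gc_stat = c("median", "mean"),
                              clamp_floor = 0) {
  gc_stat <- match.arg(gc_stat)
  stopifnot(offset > 0, clamp_floor >= 0)
  structure(list(offset = offset, gc_stat = gc_stat,
                 clamp_floor = clamp_floor),
            class = "preprocess_params")
}

#' GC-matched background correction against anti-genomic probes
#'
#' Per sample and per GC class, subtracts the chosen statistic (median or
#' mean) of the anti-genomic probe intensities of that class from every
#' genomic probe of the same class, clamping at `clamp_floor`. Anti-genomic
#' probes are dropped from the output.
#'
#' @param p probe data.frame (see [validate_probe_matrix()]).
#' @param params a [preprocess_params()].
#' @return probe data.frame of genomic probes, background-corrected.
#' @export
gc_background_correct <- function(p, params = preprocess_params()) {
  validate_probe_matrix(p)
  sam <- probe_sample_cols(p)
  stat <- switch(params$gc_stat, median = stats::median, mean = mean)
  ag <- p[p$is_antigenomic, , drop = FALSE]
  gx <- p[!p$is_antigenomic, , drop = FALSE]
  gc_missing <- setdiff(unique(gx$gc_count), unique(ag$gc_count))
  if (length(gc_missing))
    stop("no anti-genomic probes for gc_count ",
         paste(gc_missing, collapse = ", "))
  gcs <- sort(unique(ag$gc_count))
  bg <- vapply(sam, function(s)
    vapply(gcs, function(g) stat(ag[[s]][ag$gc_count == g]), numeric(1)),
    numeric(length(gcs)))
  bg <- matrix(bg, nrow = length(gcs),
               dimnames = list(as.character(gcs), sam))
  key <- as.character(gx$gc_count)
  for (s in sam)
    gx[[s]] <- pmax(gx[[s]] - bg[key, s], params$clamp_floor)
  gx
}

#' Offset-log2 transform of probe intensities
#'
#' `value -> log2(value + offset)`; a variance-stabilizing constant (default
#' 16) keeps background-corrected values near zero well-behaved.
#'
#' @inheritParams gc_background_correct
#' @return probe data.frame on the log2 scale.
#' @export
log_transform <- function(p, params = preprocess_params()) {
  sam <- probe_sample_cols(p)
  for (s in sam) {
    if (any(p[[s]] < 0))
      stop("negative intensities; background-correct and clamp first")
    p[[s]] <- log2(p[[s]] + params$offset)
  }
  p
}

#' Classical quantile normalization
#'
#' Forces every column to share the same empirical distribution: sort each
#' column, average across columns at each rank, and map back through the
#' original ranks. Tied values receive the mean of the reference values at
#' their tied ranks, so the result does not depend on input row order. A
#' single-column matrix is returned unchanged. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m numeric matrix (no missing values).
#' @return matrix of the same shape with equalized column distributions.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  stopifnot(is.numeric(m), !anyNA(m))
  if (ncol(m) <= 1) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Median summarization of probes into features
#'
#' Per feature and sample, the median of that feature's (normalized, log2)
#' probe values.
#'
#' @param p probe data.frame (genomic probes only; every feature needs at
#'   least one probe).
#' @return log2 expression matrix, features x samples.
#' @export
median_summarize <- function(p) {
  stopifnot(is.data.frame(p))
  if (any(p$is_antigenomic)) p <- p[!p$is_antigenomic, , drop = FALSE]
  if (any(!nzchar(p$feature_id))) stop("probe with empty feature_id")
  sam <- probe_sample_cols(p)
  feats <- unique(p$feature_id)
  idx <- split(seq_len(nrow(p)), factor(p$feature_id, levels = feats))
  if (any(lengths(idx) == 0)) stop("feature with no probes")
  m <- vapply(sam, function(s)
    vapply(idx, function(i) stats::median(p[[s]][i]), numeric(1)),
    numeric(length(feats)))
  m <- matrix(m, nrow = length(feats), dimnames = list(feats, sam))
  validate_expr_matrix(m)
  m
}

#' Full probe-level preprocessing chain
#'
#' GC background correction (linear scale), clamp, `+offset`/log2 transform,
#' quantile normalization of the log2 probe values computed within each
#' blood fraction separately (each fraction is analyzed independently
#' downstream), median summarization per feature, and finally
#' technical-replicate averaging.
#'
#' @param p probe data.frame including anti-genomic probes.
#' @param meta sample table (columns of `p` restricted to its sample_ids).
#' @param params a [preprocess_params()].
#' @return list with `matrix` (log2 feature x sample matrix) and `meta`
#'   (replicate rows collapsed).
#' @export
preprocess_probes <- function(p, meta, params = preprocess_params()) {
  meta <- validate_sample_table(meta, require_groups = FALSE)
  validate_probe_matrix(p)
  sam <- probe_sample_cols(p)
  missing <- setdiff(meta$sample_id, sam)
  if (length(missing))
    stop("sample(s) missing from probe table: ",
         paste(missing, collapse = ", "))
  p <- p[c("probe_id", "feature_id", "gc_count", "is_antigenomic",
           meta$sample_id)]
  p <- gc_background_correct(p, params)
  p <- log_transform(p, params)
  for (fr in unique(meta$fraction)) {
    cols <- meta$sample_id[meta$fraction == fr]
    p[cols] <- as.data.frame(quantile_normalize(as.matrix(p[cols])),
                             check.names = FALSE)
  }
  m <- median_summarize(p)
  average_replicates(m, meta)
}
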