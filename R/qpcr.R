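#' Validate a qPCR Ct table
#'
#' Long-format table with one Ct measurement per row: `mirna_id`, `group`
#' (case/control), `replicate_id`, `ct`, `is_normalizer`. Every
#' (group, replicate) combination carrying a target measurement must also
#' carry at least one normalizer measurement.
#'
#' @param q data.frame.
#' @return `q` invisibly.
#' @export
validate_qpcr_table <- function(q) {
  stopifnot(is.data.frame(q))
  need <- c("mirna_id", "group", "replicate_id", "ct", "is_normalizer")
  miss <- setdiff(need, names(q))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(q$group), GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(q$ct))) stop("Ct values must be finite")
  tgt <- unique(q[!q$is_normalizer, c("group", "replicate_id")])
  nrm <- unique(q[q$is_normalizer, c("group", "replicate_id")])
  key <- function(df) paste(df$group, df$replicate_id)
  missing <- setdiff(key(tgt), key(nrm))
  if (length(missing))
    stop("replicate(s) without normalizer measurements: ",
         paste(missing, collapse = "; "))
  invisible(q)
}

# classic pooled-variance two-sample t-test with degenerate-variance
# handling: both groups constant -> p = 1 if equal means, else ~0 with a
# warning
pooled_t_p <- function(x, y) {
  if (stats::var(x) + stats::var(y) < .Machine$double.eps) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
    warning("zero variance with unequal means: p below machine precision")
    return(.Machine$double.xmin)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Relative qPCR quantification of one miRNA: 2^(-deltaCt) statistics
#'
#' Per (group, replicate): `deltaCt = Ct_target - mean(Ct of normalizers in
#' that replicate)`, quantified as `2^(-deltaCt)`. The fold change is the
#' mean case value over the mean control value, and the p-value a two-sided
#' pooled-variance Student t-test on the replicate values.
#'
#' @param q validated qPCR table.
#' @param mirna target miRNA id (must not be a normalizer).
#' @return list: `fold_change`, `p_value`, `values` (named list of case and
#'   control replicate 2^(-deltaCt) values).
#' @export
delta_ct_fold_change <- function(q, mirna) {
  validate_qpcr_table(q)
  tgt <- q[!q$is_normalizer & q$mirna_id == mirna, , drop = FALSE]
  if (!nrow(tgt)) stop("no measurements for miRNA ", mirna)
  nrm <- q[q$is_normalizer, , drop = FALSE]
  nrm_mean <- tapply(nrm$ct, paste(nrm$group, nrm$replicate_id), mean)
  key <- paste(tgt$group, tgt$replicate_id)
  if (anyNA(nrm_mean[key])) stop("missing normalizer for a replicate")
  val <- as.vector(2^(-(tgt$ct - nrm_mean[key])))
  case_v <- val[tgt$group == "case"]
  ctrl_v <- val[tgt$group == "control"]
  if (length(case_v) < 2 || length(ctrl_v) < 2)
    stop("need at least 2 replicates per group for miRNA ", mirna)
  list(fold_change = mean(case_v) / mean(ctrl_v),
       p_value = pooled_t_p(case_v, ctrl_v),
       values = list(case = case_v, control = ctrl_v))
}

#' Summarize every target miRNA in a qPCR table
#' @param q validated qPCR table.
#' @return data.frame: mirna_id, fold_change, p_value.
#' @export
qpcr_summary <- function(q) {
  validate_qpcr_table(q)
  ids <- unique(q$mirna_id[!q$is_normalizer])
  do.call(rbind, lapply(ids, function(id) {
    r <- delta_ct_fold_change(q, id)
    data.frame(mirna_id = id, fold_change = r$fold_change,
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
}

#' Cross-platform fold-change concordance
#'
#' Paired two-sided Student t-test on the per-miRNA difference of log2 fold
#' changes between two platforms (log2 so up- and down-regulation weigh
#' symmetrically). A large p indicates no detectable platform disagreement.
#'
#' @param array_fc,qpcr_fc positive per-miRNA fold changes over the same
#'   miRNA set, aligned (by names when both are named).
#' @return list: `p_value`, `mean_log2_difference`, `n`.
#' @export
platform_concordance <- function(array_fc, qpcr_fc) {
  if (!is.null(names(array_fc)) && !is.null(names(qpcr_fc))) {
    stopifnot(setequal(names(array_fc), names(qpcr_fc)))
    qpcr_fc <- qpcr_fc[names(array_fc)]
  }
  stopifnot(length(array_fc) == length(qpcr_fc), length(array_fc) >= 2,
            all(array_fc > 0), all(qpcr_fc > 0))
  d <- log2(array_fc) - log2(qpcr_fc)
  if (stats::var(d) < .Machine$double.eps) {
    if (isTRUE(all.equal(mean(d), 0, tolerance = 1e-12)))
      return(list(p_value = 1, mean_log2_difference = 0, n = length(d)))
    warning("constant nonzero platform difference: p below machine precision")
    return(list(p_value = .Machine$double.xmin,
                mean_log2_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(d)
  list(p_value = tt$p.value, mean_log2_difference = unname(tt$estimate),
       n = length(d))
}
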