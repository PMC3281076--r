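#' @title Tabular readers and writers
#' @description All tabular inputs and outputs use one dialect: tab-separated
#'   UTF-8 text with a header row; lines starting with `#` are ignored.
#'   Expression matrices are numeric matrices on the log2 scale with feature
#'   rownames and sample colnames. Writers serialize at 15 significant digits
#'   so a read/write round trip is lossless well beyond 12 significant digits.
#' @name circumir-io
NULL

GROUPS    <- c("case", "control")
FRACTIONS <- c("platelet", "microvesicle", "pbmc")

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sample metadata table
#'
#' @param meta data.frame with columns `sample_id`, `group` (case/control),
#'   `fraction` (platelet/microvesicle/pbmc) and optionally `replicate_of`
#'   (the sample_id of the technical-replicate parent, `NA` otherwise).
#' @param require_groups if `TRUE` (default), require at least 2 cases and 2
#'   controls among non-replicate samples.
#' @return `meta`, with `replicate_of` added (all `NA`) if absent.
#' @export
validate_sample_table <- function(meta, require_groups = TRUE) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "group", "fraction")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(meta$group), GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$fraction), FRACTIONS)
  if (length(bad)) stop("unknown fraction label(s): ",
                        paste(bad, collapse = ", "))
  if (!"replicate_of" %in% names(meta)) meta$replicate_of <- NA_character_
  meta$replicate_of[meta$replicate_of %in% c("", "NA")] <- NA_character_
  ref <- meta$replicate_of[!is.na(meta$replicate_of)]
  orphan <- setdiff(ref, meta$sample_id)
  if (length(orphan)) stop("replicate_of refers to unknown sample_id: ",
                           paste(orphan, collapse = ", "))
  if (require_groups) {
    eff <- meta[is.na(meta$replicate_of), ]
    if (sum(eff$group == "case") < 2 || sum(eff$group == "control") < 2)
      stop("need at least 2 cases and 2 controls")
  }
  meta
}

#' Read a sample metadata TSV
#' @param path TSV with columns sample_id, group, fraction[, replicate_of].
#' @inheritParams validate_sample_table
#' @return validated data.frame.
#' @export
read_sample_table <- function(path, require_groups = TRUE) {
  validate_sample_table(read_tsv(path), require_groups = require_groups)
}

#' Write a sample metadata TSV
#' @param meta sample table data.frame.
#' @param path output path.
#' @export
write_sample_table <- function(meta, path) write_tsv(meta, path)

#' Check an expression matrix invariant set
#'
#' Numeric, finite, log2-scale matrix with unique feature rownames and sample
#' colnames.
#' @param m matrix.
#' @return `m` invisibly.
#' @export
validate_expr_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids")
  if (any(!is.finite(m))) stop("expression matrix has missing/non-finite values")
  invisible(m)
}

#' Read a log2 expression matrix, aligned to sample metadata
#'
#' The file's first column holds feature ids; remaining columns are samples.
#' The result is restricted to, and ordered by, the metadata sample order;
#' extra file columns are dropped with a message.
#'
#' @param path TSV path.
#' @param meta sample table; every `meta$sample_id` must be a file column.
#' @return numeric matrix (features x samples), log2 scale.
#' @export
read_expr_matrix <- function(path, meta) {
  meta <- validate_sample_table(meta, require_groups = FALSE)
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("expression TSV needs a feature column plus samples")
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats)) stop("duplicated feature ids in ", path)
  have <- names(df)[-1]
  missing <- setdiff(meta$sample_id, have)
  if (length(missing))
    stop("sample(s) in metadata but not in ", path, ": ",
         paste(missing, collapse = ", "))
  extra <- setdiff(have, meta$sample_id)
  if (length(extra))
    message("dropping ", length(extra), " column(s) not in metadata: ",
            paste(extra, collapse = ", "))
  vals <- df[meta$sample_id]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop("non-numeric value '", vals[[j]][bad[1]], "' at feature '",
           feats[bad[1]], "', sample '", names(vals)[j], "'")
    vals[[j]] <- x
  }
  m <- as.matrix(vals)
  rownames(m) <- feats
  validate_expr_matrix(m)
  m
}

#' Write a log2 expression matrix as TSV
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_expr_matrix <- function(m, path) {
  validate_expr_matrix(m)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Validate a probe-level matrix
#'
#' A probe table is a data.frame whose first four columns are `probe_id`,
#' `feature_id` (empty for anti-genomic background probes), `gc_count` and
#' `is_antigenomic`, followed by one nonnegative linear-scale intensity
#' column per sample. Every GC class present among genomic probes must also
#' be represented among the anti-genomic probes, so GC-matched background
#' correction is always defined.
#'
#' @param p probe data.frame.
#' @return `p` invisibly.
#' @export
validate_probe_matrix <- function(p) {
  stopifnot(is.data.frame(p))
  need <- c("probe_id", "feature_id", "gc_count", "is_antigenomic")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("probe table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(p$probe_id)) stop("duplicated probe_id")
  if (any(p$gc_count < 0)) stop("gc_count must be >= 0")
  sam <- probe_sample_cols(p)
  if (!length(sam)) stop("probe table has no sample columns")
  vals <- as.matrix(p[sam])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("probe intensities must be finite numerics")
  if (any(vals < 0)) stop("probe intensities must be >= 0")
  gc_genomic <- unique(p$gc_count[!p$is_antigenomic])
  gc_bg      <- unique(p$gc_count[p$is_antigenomic])
  orphan <- setdiff(gc_genomic, gc_bg)
  if (length(orphan))
    stop("no anti-genomic probes for gc_count ", paste(orphan, collapse = ", "))
  invisible(p)
}

probe_sample_cols <- function(p) {
  setdiff(names(p), c("probe_id", "feature_id", "gc_count", "is_antigenomic"))
}

#' Read a probe-level TSV
#' @param path TSV with probe_id, feature_id, gc_count, is_antigenomic and one
#'   intensity column per sample.
#' @return validated probe data.frame (`is_antigenomic` coerced to logical).
#' @export
read_probe_matrix <- function(path) {
  p <- read_tsv(path)
  if ("is_antigenomic" %in% names(p))
    p$is_antigenomic <- as.logical(p$is_antigenomic) |
      p$is_antigenomic %in% c("1", "TRUE", "true")
  p$feature_id[is.na(p$feature_id)] <- ""
  validate_probe_matrix(p)
  p
}

#' Write a probe-level TSV
#' @param p probe data.frame.
#' @param path output path.
#' @export
write_probe_matrix <- function(p, path) write_tsv(p, path)

#' Read a miRNA-to-target-gene map
#'
#' Two-column TSV (miRNA id, gene id), one pair per row. miRNAs that end up
#' with no targets are dropped with a warning.
#'
#' @param path TSV path.
#' @return named list: miRNA id -> character vector of unique gene ids.
#' @export
read_target_map <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("target map needs two columns: mirna_id, gene_id")
  make_target_map(df[[1]], df[[2]])
}

#' Build a target map from paired vectors
#' @param mirna_id,gene_id character vectors of equal length.
#' @return named list of unique gene-id sets.
#' @export
make_target_map <- function(mirna_id, gene_id) {
  keep <- !is.na(mirna_id) & !is.na(gene_id) & nzchar(gene_id)
  dropped <- setdiff(unique(mirna_id), unique(mirna_id[keep]))
  if (length(dropped))
    warning("dropping miRNA(s) with no targets: ",
            paste(dropped, collapse = ", "))
  lapply(split(gene_id[keep], mirna_id[keep]), function(g) unique(g))
}

#' Write a target map as two-column TSV
#' @param tm named list of gene-id vectors.
#' @param path output path.
#' @export
write_target_map <- function(tm, path) {
  df <- data.frame(
    mirna_id = rep(names(tm), lengths(tm)),
    gene_id  = unlist(tm, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read genomic loci from a BED file
#'
#' BED coordinates (0-based, half-open) are kept as-is internally. Only the
#' first six columns are used; `name` becomes the feature id.
#'
#' @param path BED path (3-6 columns, no header).
#' @return data.frame with feature_id, chrom, start, end, strand.
#' @export
read_bed_loci <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least chrom, start, end")
  out <- data.frame(
    feature_id = if (ncol(df) >= 4) as.character(df[[4]])
                 else paste0("locus", seq_len(nrow(df))),
    chrom  = as.character(df[[1]]),
    start  = as.integer(df[[2]]),
    end    = as.integer(df[[3]]),
    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "unknown",
    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$start >= out$end))
    stop("BED intervals must satisfy 0 <= start < end")
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  out
}

#' Average technical replicates into their parent sample
#'
#' Columns whose metadata `replicate_of` names a parent sample are averaged
#' (arithmetic mean on the log2 scale) together with the parent column, which
#' keeps the parent's sample id; other columns pass through unchanged.
#'
#' @param m log2 expression matrix.
#' @param meta sample table with `replicate_of`.
#' @return list with `matrix` (one column per effective sample) and `meta`
#'   (replicate rows removed).
#' @export
average_replicates <- function(m, meta) {
  validate_expr_matrix(m)
  meta <- validate_sample_table(meta, require_groups = FALSE)
  stopifnot(all(meta$sample_id %in% colnames(m)))
  parent <- ifelse(is.na(meta$replicate_of), meta$sample_id, meta$replicate_of)
  keep <- meta[is.na(meta$replicate_of), , drop = FALSE]
  out <- vapply(keep$sample_id, function(sid) {
    members <- meta$sample_id[parent == sid]
    rowMeans(m[, members, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), keep$sample_id))
  list(matrix = out, meta = keep)
}
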