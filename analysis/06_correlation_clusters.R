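# Correlation structure of the selected biomarkers: Pearson correlations
# across all 40 samples, complete-linkage clustering with a min-pairwise
# r > 0.6 validation, a two-group sample dendrogram, and a genomic
# co-localization check against synthetic loci.
source("analysis/00_common.R")
need_data("expr.tsv", "meta.tsv")
panel_path <- file.path(OUT_DIR, "consensus_panel.tsv")
if (!file.exists(panel_path))
  stop("run analysis/04_consensus_panel.R first", call. = FALSE)

meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))
m <- read_expr_matrix(file.path(DATA_DIR, "expr.tsv"), meta)
ptab <- utils::read.delim(panel_path)
panel <- ptab$feature_id[ptab$selected]

cc <- correlation_clusters(m, panel, r_threshold = 0.6)
print(cc)
jsonlite::write_json(
  list(clusters = cc$clusters, summary = cc$summary,
       unassigned = as.list(cc$unassigned)),
  file.path(OUT_DIR, "biomarker_clusters.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

hs <- hier_cluster_samples(m[panel, , drop = FALSE], meta)
cat(sprintf(
  "two-group sample cut misclassifies %d / %d samples (%s)\n",
  hs$misclassified, ncol(m),
  if (length(hs$misclassified_ids))
    paste(hs$misclassified_ids, collapse = ", ") else "none"))

# synthetic loci: place the first cluster's first two members 50 kb apart
if (length(cc$clusters)) {
  ids <- utils::head(cc$clusters[[1]], 2)
  loci <- data.frame(
    feature_id = c(ids, "mir-far"),
    chrom = c("chrX", "chrX", "chr7"),
    start = c(1e6, 1e6 + 5e4, 2e6),
    end = c(1e6 + 80, 1e6 + 5e4 + 80, 2e6 + 80))
  near <- colocalize(loci, max_gap_bp = 220000)
  cat("pairs within 220 kb on one chromosome:\n")
  print(near, row.names = FALSE)
}
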