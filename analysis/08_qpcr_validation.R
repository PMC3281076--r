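# qPCR validation arithmetic on a synthetic Ct table for eight panel
# members: per-replicate delta-Ct against a normalizer panel, 2^(-deltaCt)
# fold changes with Student t-tests, and the paired cross-platform
# concordance test against the array fold changes.
source("analysis/00_common.R")
need_data("expr.tsv", "meta.tsv")
panel_path <- file.path(OUT_DIR, "consensus_panel.tsv")
if (!file.exists(panel_path))
  stop("run analysis/04_consensus_panel.R first", call. = FALSE)

meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))
m <- read_expr_matrix(file.path(DATA_DIR, "expr.tsv"), meta)
ptab <- utils::read.delim(panel_path)
panel <- ptab$feature_id[ptab$selected]
picked <- utils::head(panel, 8)
array_fc <- fold_change(m, meta$group)[picked]

# synthesize Ct measurements consistent with the array fold changes:
# 2 RT x 2 PCR replicates per pooled group, normalizer Ct ~20, target
# delta-Ct shifted down by log2(FC) in cases, 0.15-cycle replicate noise
set.seed(stage_seed(SEED, "qpcr"))
rows <- list()
for (g in c("case", "control")) {
  for (r in paste0("r", 1:4)) {
    norm_ct <- rnorm(4, mean = 20, sd = 0.1)
    for (k in seq_along(norm_ct))
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = paste0("norm", k), group = g, replicate_id = r,
        ct = norm_ct[k], is_normalizer = TRUE)
    for (id in picked) {
      base_dct <- 4
      dct <- base_dct - (g == "case") * log2(array_fc[[id]]) +
        rnorm(1, 0, 0.15)
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = id, group = g, replicate_id = r,
        ct = mean(norm_ct) + dct, is_normalizer = FALSE)
    }
  }
}
qtab <- do.call(rbind, rows)
validate_qpcr_table(qtab)

qres <- qpcr_summary(qtab)
qres$array_fold_change <- unname(array_fc[qres$mirna_id])
qres$validated <- qres$p_value < 0.05 & (qres$fold_change > 1) ==
  (qres$array_fold_change > 1)
print(qres, row.names = FALSE)
utils::write.table(qres, file.path(OUT_DIR, "qpcr_validation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

conc <- platform_concordance(array_fc,
                             setNames(qres$fold_change, qres$mirna_id))
cat(sprintf(
  "validated %d / %d assays; platform concordance: paired t p = %.2f (mean log2 diff %.3f)\n",
  sum(qres$validated), nrow(qres), conc$p_value, conc$mean_log2_difference))
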