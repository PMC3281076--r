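# A single SAM pass over the preprocessed platelet matrix at FDR 1%:
# modified t-scores, permutation-calibrated delta, q-values, fold changes.
source("analysis/00_common.R")
need_data("expr.tsv", "meta.tsv", "truth.tsv")

meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))
m <- read_expr_matrix(file.path(DATA_DIR, "expr.tsv"), meta)
truth <- utils::read.delim(file.path(DATA_DIR, "truth.tsv"))

res <- sam_calibrate(m, meta$group,
                     sam_params(fdr_target = 0.01, n_permutations = 500,
                                seed = stage_seed(SEED, "sam")))
print(res)
utils::write.table(res$table, file.path(OUT_DIR, "sam_platelet.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

called <- res$table[res$table$called, ]
up_share <- mean(called$direction == "up")
hits <- called$feature_id %in% truth$feature_id[truth$is_de]
cat(sprintf("%d features called at FDR <= 1%%; %.0f%% up-regulated\n",
            nrow(called), 100 * up_share))
cat(sprintf("of those, %d are planted biomarkers and %d are false calls\n",
            sum(hits), sum(!hits)))
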