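# Resampling-consensus biomarker derivation: 100 cycles of SAM on random
# 18-case/18-control subsamples; features called in >= 90% of the cycles
# form the biomarker panel.
source("analysis/00_common.R")
need_data("expr.tsv", "meta.tsv", "truth.tsv")

meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))
m <- read_expr_matrix(file.path(DATA_DIR, "expr.tsv"), meta)
truth <- utils::read.delim(file.path(DATA_DIR, "truth.tsv"))

panel <- derive_consensus(m, meta,
                          consensus_params(seed = stage_seed(SEED, "consensus")))
print(panel)
utils::write.table(panel$table, file.path(OUT_DIR, "consensus_panel.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

de_ids <- truth$feature_id[truth$is_de]
freq <- setNames(panel$table$frequency, panel$table$feature_id)
cat(sprintf("planted biomarkers at frequency >= 0.9: %d / %d\n",
            sum(freq[de_ids] >= 0.9), length(de_ids)))
cat(sprintf("null features at frequency >= 0.9: %d / %d\n",
            sum(freq[setdiff(names(freq), de_ids)] >= 0.9),
            length(freq) - length(de_ids)))
cat("panel members:", paste(panel$selected, collapse = ", "), "\n")
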