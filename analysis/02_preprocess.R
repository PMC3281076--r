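# Probe-level preprocessing: GC-matched background subtraction against the
# anti-genomic controls, +16/log2 transform, quantile normalization within
# the fraction, median summarization per feature, replicate averaging.
source("analysis/00_common.R")
need_data("probes.tsv", "meta.tsv", "feature_truth.tsv")

probes <- read_probe_matrix(file.path(DATA_DIR, "probes.tsv"))
meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))

pp <- preprocess_probes(probes, meta)
write_expr_matrix(pp$matrix, file.path(DATA_DIR, "expr.tsv"))

truth <- read_expr_matrix(file.path(DATA_DIR, "feature_truth.tsv"), pp$meta)
shared <- intersect(rownames(pp$matrix), rownames(truth))
r <- cor(as.vector(pp$matrix[shared, ]),
         as.vector(log2(2^truth[shared, ] + 16)))
cat(sprintf("summarized %d features x %d samples\n",
            nrow(pp$matrix), ncol(pp$matrix)))
cat(sprintf(
  "correlation with the generating signal (after the +16/log2 map): %.4f\n",
  r))
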