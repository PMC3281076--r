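# Nested Monte-Carlo cross-validation: 100 repetitions of an 18:2-per-class
# split, in-fold consensus feature selection on 16:16 inner subsets, an
# RBF-kernel SVM trained on the standardized panel, and performance from
# the aggregated confusion matrix.
source("analysis/00_common.R")
need_data("expr.tsv", "meta.tsv")

meta <- read_sample_table(file.path(DATA_DIR, "meta.tsv"))
m <- read_expr_matrix(file.path(DATA_DIR, "expr.tsv"), meta)

ev <- evaluate_classifier(m, meta,
  eval_params(n_repetitions = 100, inner_consensus_iterations = 10,
              inner_sam_params = sam_params(n_permutations = 100),
              seed = stage_seed(SEED, "evaluate")))
print(ev)
jsonlite::write_json(
  list(confusion = ev$confusion, metrics = ev$metrics,
       per_sample = ev$per_sample),
  file.path(OUT_DIR, "classifier_eval.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("median in-fold panel size: %d features\n",
            as.integer(median(lengths(ev$panels)))))
worst <- misclassification_report(ev)
worst <- worst[worst$times_misclassified > 0, ]
if (nrow(worst)) {
  cat("samples ever misclassified:\n")
  print(utils::head(worst, 5), row.names = FALSE)
} else cat("no sample was ever misclassified\n")
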