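# Generate the synthetic study: 20 UC-like cases and 20 controls profiled
# over 847 miRNA features at the probe level, with 31 planted up-regulated
# platelet biomarkers (log2 FC 0.5-1) of which 28 sit in four correlated
# blocks (rho = 0.75), emulating the structure the downstream analyses
# assume.
source("analysis/00_common.R")

design <- simulation_design(seed = stage_seed(SEED, "study"))
sim <- simulate_probe_matrix(design, fraction = "platelet",
                             probe_noise_sd = 2)

write_probe_matrix(sim$probes, file.path(DATA_DIR, "probes.tsv"))
write_sample_table(sim$meta, file.path(DATA_DIR, "meta.tsv"))
write_expr_matrix(sim$feature, file.path(DATA_DIR, "feature_truth.tsv"))
utils::write.table(sim$truth, file.path(DATA_DIR, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "wrote %d probes (%d features x %d probes + %d anti-genomic) for %d samples\n",
  nrow(sim$probes), design$n_features, design$probes_per_feature,
  sum(sim$probes$is_antigenomic), nrow(sim$meta)))
cat(sprintf("planted biomarkers: %d up-regulated, fold changes %.2f-%.2f\n",
            sum(sim$truth$is_de),
            min(sim$truth$fold_change[sim$truth$is_de]),
            max(sim$truth$fold_change[sim$truth$is_de])))
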