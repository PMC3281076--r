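# Links from the biomarker panel to gene regulation: the cohort
# demographics exact tests, a synthetic miRNA->target map, the
# down-regulated-target anti-correlation test on a simulated mRNA matrix
# with planted down-regulation enriched among panel targets, and a
# hypergeometric term-enrichment scan.
source("analysis/00_common.R")
panel_path <- file.path(OUT_DIR, "consensus_panel.tsv")
if (!file.exists(panel_path))
  stop("run analysis/04_consensus_panel.R first", call. = FALSE)
ptab <- utils::read.delim(panel_path)
panel <- ptab$feature_id[ptab$selected]

cat(sprintf("cohort GI-history contrast (8/20 vs 0/20): p = %.4f\n",
            fisher_one_sided(8, 12, 0, 20)))
cat(sprintf("cohort non-GI-history contrast (6/20 vs 0/20): p = %.4f\n",
            fisher_one_sided(6, 14, 0, 20)))

n_genes <- 3304   # size of the non-redundant target universe emulated
tm <- simulate_target_map(847, n_genes, 120,
                          seed = stage_seed(SEED, "targets"))

# mRNA matrix: 9 samples (4 controls / 5 cases) with down-regulated genes
# 3x enriched among the panel's predicted targets
tgt_genes <- unique(unlist(tm[intersect(panel, names(tm))]))
genes <- sprintf("gene-%05d", seq_len(n_genes))
set.seed(stage_seed(SEED, "mrna_truth"))
n_down <- 300
w <- ifelse(genes %in% tgt_genes, 3, 1)
down_genes <- sample(genes, n_down, prob = w)
d <- simulation_design(n_cases = 5, n_controls = 4, n_features = n_genes,
                       n_de = n_down, de_direction = "down",
                       log2_fc_range = c(1.5, 2.5), corr_blocks = list(),
                       seed = stage_seed(SEED, "mrna"))
mrna <- simulate_feature_matrix(d)
# re-home the planted down-regulation onto the target-enriched gene sample
# (the generator plants DE in its first n_de rows)
rownames(mrna$matrix) <- c(down_genes, setdiff(genes, down_genes))

td <- target_downregulation_test(mrna$matrix, mrna$meta$group, tm, panel,
                                 fdr = 0.001, fc_min = 2,
                                 sam_seed = stage_seed(SEED, "mrna_sam"),
                                 n_permutations = 126)
print(td$counts)
cat(sprintf(
  "target down-regulation: %d / %d targets down; Fisher p = %.3g, binomial p = %.3g\n",
  td$n_down_targets, td$n_targets, td$p_fisher, td$p_binomial))
jsonlite::write_json(
  list(counts = as.data.frame(td$counts), p_fisher = td$p_fisher,
       p_binomial = td$p_binomial, p0 = td$p0),
  file.path(OUT_DIR, "target_enrichment.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

# term enrichment of the down-regulated targets over synthetic categories
down_called <- with(td$sam$table, feature_id[called & fold_change <= 0.5])
down_tgts <- intersect(down_called, tgt_genes)
set.seed(stage_seed(SEED, "categories"))
cats <- c(list(down_target_like = unique(c(down_tgts,
                                           sample(genes, 150)))),
          lapply(setNames(1:6, paste0("random_term_", 1:6)),
                 function(i) sample(genes, 200)))
te <- term_enrichment(down_tgts, cats, genes)
cat("top enrichment terms:\n")
print(utils::head(te, 3), row.names = FALSE)
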