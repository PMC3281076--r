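# circumir

Resampling-based discovery and evaluation of circulating miRNA biomarkers
from case/control blood-fraction microarray data.

Blood sub-compartments — platelets, peripheral blood mononuclear cells
(PBMC) and micro-vesicles — each carry a distinct miRNA cargo, and shifts
in that cargo can mark disease non-invasively. `circumir` implements, as a
tested R package plus a numbered analysis workflow, the full derivation
chain for such a marker panel in a 20-case / 20-control cohort profiled
over ~847 miRNAs:

* **Preprocessing** (`preprocess_probes()`): background subtraction against
  anti-genomic control probes matched by GC content, `log2(x + 16)`
  transform, quantile normalization within each blood fraction, median
  summarization of probes into features, technical-replicate averaging.
* **Differential expression** (`sam_calibrate()`): two-class unpaired
  Significance Analysis of Microarrays. Scores are
  `d_i = (mean_case − mean_control) / (s_i + s0)` with `s_i` the pooled
  standard error and `s0` a tuned stabilization constant; the FDR is
  estimated from label permutations (`pi0 · median false calls / called`)
  and features are called at the smallest threshold `delta` meeting the
  target FDR (default 1%).
* **Consensus selection** (`derive_consensus()`): SAM is re-run on 100
  random 18:18 subsamples (a 9:1 split per class) and features called in
  ≥ 90% of iterations form the biomarker panel — stability selection, in
  modern terms.
* **Performance estimation** (`evaluate_classifier()`): nested Monte-Carlo
  cross-validation — 100 repetitions of an 18:2-per-class train/test
  split, consensus feature selection redone *inside* each training set
  (16:16 inner subsets), an RBF-kernel SVM (`e1071`, cost 1,
  gamma = 1/panel size) on standardized features, and accuracy /
  sensitivity / specificity / PPV / NPV from the aggregated confusion
  matrix, so test samples never inform the panel.
* **Structure and downstream biology**: Pearson correlation clusters among
  panel members with a min-pairwise-r > 0.6 rule
  (`correlation_clusters()`), genomic co-localization (`colocalize()`),
  one-sided Fisher / binomial / hypergeometric enrichment tests
  (`fisher_one_sided()`, `binomial_tail()`, `term_enrichment()`), the
  miRNA-target down-regulation test (`target_downregulation_test()`), and
  qPCR ΔCt validation arithmetic (`delta_ct_fold_change()`,
  `platform_concordance()`).

A synthetic-data generator (`simulation_design()`,
`simulate_probe_matrix()`) emulates the study conditions — 31 planted
up-regulated biomarkers (log2 FC 0.5–1) among 847 features, four
correlated biomarker blocks at r = 0.75 — so every stage is testable
offline, with planted ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic study and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1         # probe-level study data
Rscript analysis/02_preprocess.R --seed 1
Rscript analysis/03_differential_expression.R --seed 1
Rscript analysis/04_consensus_panel.R --seed 1
Rscript analysis/05_classifier_evaluation.R --seed 1
Rscript analysis/06_correlation_clusters.R --seed 1
Rscript analysis/07_target_enrichment.R --seed 1
Rscript analysis/08_qpcr_validation.R --seed 1
```

With seed 1 this prints, along the way:

```
SAM two-class result: 847 features, 28 called at FDR <= 0.01 (s0 = 0.177, delta = 0.636, pi0 = 1, 500 permutations)
28 features called at FDR <= 1%; 100% up-regulated
of those, 27 are planted biomarkers and 1 are false calls

Consensus panel: 20 / 847 features at frequency >= 0.9 over 100 iterations
planted biomarkers at frequency >= 0.9: 20 / 31
null features at frequency >= 0.9: 0 / 816

Nested CV over 100 repetitions: tp=200 fp=0 tn=200 fn=0
accuracy 100.0%, sensitivity 100.0%, specificity 100.0%

Correlation clusters (min pairwise r > 0.6): 4 cluster(s), 3 unassigned feature(s)
 cluster size min_pairwise_r mean_pairwise_r max_pairwise_p
       1    7      0.7905918       0.8364090   1.290498e-09
...
validated 8 / 8 assays; platform concordance: paired t p = 0.98 (mean log2 diff 0.001)
```

Reading these numbers: a single SAM pass at FDR 1% finds 28 of the 31
planted markers with one false call; the consensus filter keeps the 20
markers stable across subsamples (the weakest planted fold changes, near
log2 FC 0.5, are below the power of an 18:18 split at 1% FDR — see the
methods vignette) while admitting zero null features; the panel separates
the classes perfectly under nested cross-validation; its members fall into
four correlation clusters matching the planted blocks; and the synthetic
qPCR assay validates all eight tested markers with no detectable platform
disagreement.

The same chain is available as one call on a config:

```r
library(circumir)
run_pipeline(pipeline_config(out_dir = "results/run1", seed = 1))
```

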