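#' Assemble a pipeline configuration
#'
#' One master seed drives every randomized stage through stage-name-keyed
#' derived streams, so a run is fully reproducible from `(config, seed)`.
#' Stage parameter lists override the corresponding constructor defaults.
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed.
#' @param fraction blood fraction analyzed.
#' @param design named overrides for [simulation_design()].
#' @param input optional list with `expr` and `meta` TSV paths; when given,
#'   simulation and probe preprocessing are skipped and the matrix is read
#'   from disk.
#' @param sam,consensus,evaluate,cluster,enrich named stage overrides
#'   ([sam_params()], [consensus_params()], [eval_params()], the
#'   `r_threshold` of [correlation_clusters()], and the synthetic target-map
#'   /mRNA settings of the enrichment stage).
#' @param stages subset of pipeline stages to run, in fixed order.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1, fraction = "platelet",
                            design = list(), input = NULL,
                            sam = list(), consensus = list(),
                            evaluate = list(), cluster = list(),
                            enrich = list(),
                            stages = c("simulate", "preprocess", "sam",
                                       "consensus", "evaluate", "cluster",
                                       "enrich")) {
  if (!fraction %in% FRACTIONS)
    stop("unknown fraction label: ", fraction)
  bad <- setdiff(stages, c("simulate", "preprocess", "sam", "consensus",
                           "evaluate", "cluster", "enrich"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = seed, fraction = fraction,
                 design = design, input = input, sam = sam,
                 consensus = consensus, evaluate = evaluate,
                 cluster = cluster, enrich = enrich, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return `"pipeline_config"` object (validated).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, as configured: synthetic-data generation (probe and feature
#' level), probe preprocessing, a single SAM pass, resampling-consensus
#' biomarker selection, nested Monte-Carlo classifier evaluation,
#' correlation-cluster extraction over the selected panel, and a synthetic
#' target-map enrichment test. Every stage writes its table under the run
#' directory and a machine-readable `summary.json` collects the headline
#' results. Identical config and seed reproduce the run byte for byte.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, the summary list; side effect: populated run
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(seed = config$seed, fraction = config$fraction,
                  stages = as.list(config$stages))

  design <- run_stage("simulate", do.call(simulation_design, utils::modifyList(
    list(seed = stage_seed(config$seed, "simulate")), config$design)))

  if (!is.null(config$input)) {
    meta <- run_stage("preprocess", read_sample_table(config$input$meta))
    meta <- meta[meta$fraction == config$fraction, , drop = FALSE]
    if (!nrow(meta)) stop("pipeline stage 'preprocess' failed: no samples ",
                          "for fraction ", config$fraction, call. = FALSE)
    m <- run_stage("preprocess", read_expr_matrix(config$input$expr, meta))
    avg <- run_stage("preprocess", average_replicates(m, meta))
    m <- avg$matrix; meta <- avg$meta
    truth <- NULL
  } else {
    sim <- NULL
    if ("simulate" %in% config$stages) {
      sim <- run_stage("simulate",
                       simulate_probe_matrix(design, config$fraction))
      write_probe_matrix(sim$probes, out("probes.tsv"))
      write_sample_table(sim$meta, out("meta.tsv"))
      write_tsv(sim$truth, out("truth.tsv"))
      write_expr_matrix(sim$feature, out("feature_truth.tsv"))
    } else {
      stop("pipeline needs either an input block or the simulate stage")
    }
    if ("preprocess" %in% config$stages) {
      pp <- run_stage("preprocess", preprocess_probes(sim$probes, sim$meta))
      m <- pp$matrix; meta <- pp$meta
    } else {
      m <- sim$feature; meta <- sim$meta
    }
    truth <- sim$truth
  }
  write_expr_matrix(m, out("expr.tsv"))
  write_sample_table(meta, out("meta.tsv"))

  sam_res <- NULL
  if ("sam" %in% config$stages) {
    sp <- do.call(sam_params, utils::modifyList(
      list(n_permutations = 200, seed = stage_seed(config$seed, "sam")),
      config$sam))
    sam_res <- run_stage("sam", sam_calibrate(m, meta$group, sp))
    write_tsv(sam_res$table, out("sam.tsv"))
    summary$sam <- list(n_called = sum(sam_res$table$called),
                        s0 = sam_res$s0, pi0 = sam_res$pi0)
  }

  panel <- NULL
  if ("consensus" %in% config$stages) {
    cp <- do.call(consensus_params, utils::modifyList(
      list(seed = stage_seed(config$seed, "consensus")), config$consensus))
    panel <- run_stage("consensus", derive_consensus(m, meta, cp))
    write_tsv(panel$table, out("panel.tsv"))
    summary$consensus <- list(n_selected = length(panel$selected),
                              selected = as.list(panel$selected),
                              threshold = panel$threshold,
                              n_iterations = panel$n_iterations)
  }

  if ("evaluate" %in% config$stages) {
    ep <- do.call(eval_params, utils::modifyList(
      list(seed = stage_seed(config$seed, "evaluate")), config$evaluate))
    ev <- run_stage("evaluate", evaluate_classifier(m, meta, ep))
    jsonlite::write_json(
      list(confusion = ev$confusion, metrics = ev$metrics,
           per_sample = ev$per_sample, fallbacks = as.list(ev$fallbacks)),
      out("eval.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$evaluate <- c(ev$confusion[c("tp", "fp", "tn", "fn")],
                          ev$metrics)
  }

  if ("cluster" %in% config$stages) {
    feats <- if (!is.null(panel) && length(panel$selected) >= 2)
      panel$selected else rownames(m)
    rthr <- if (!is.null(config$cluster$r_threshold))
      config$cluster$r_threshold else 0.6
    cc <- run_stage("cluster", correlation_clusters(m, feats, rthr))
    hs <- run_stage("cluster", hier_cluster_samples(
      m[feats, , drop = FALSE], meta))
    jsonlite::write_json(
      list(clusters = cc$clusters, summary = cc$summary,
           unassigned = as.list(cc$unassigned),
           sample_cut_misclassified = hs$misclassified,
           misclassified_ids = as.list(hs$misclassified_ids)),
      out("clusters.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$cluster <- list(n_clusters = length(cc$clusters),
                            sizes = as.list(lengths(cc$clusters)),
                            sample_cut_misclassified = hs$misclassified)
  }

  if ("enrich" %in% config$stages) {
    en <- config$enrich
    n_genes <- if (!is.null(en$n_genes)) en$n_genes else 400
    tpm <- if (!is.null(en$targets_per_mirna)) en$targets_per_mirna else 25
    tm <- run_stage("enrich", simulate_target_map(
      design$n_features, n_genes, tpm,
      seed = stage_seed(config$seed, "target_map")))
    write_target_map(tm, out("targets.tsv"))
    mrna_design <- do.call(simulation_design, utils::modifyList(
      list(n_cases = design$n_cases, n_controls = design$n_controls,
           n_features = n_genes, n_de = max(2, n_genes %/% 10),
           de_direction = "down", corr_blocks = list(),
           seed = stage_seed(config$seed, "mrna")),
      if (!is.null(en$mrna_design)) en$mrna_design else list()))
    mrna <- run_stage("enrich", simulate_feature_matrix(mrna_design))
    rownames(mrna$matrix) <- sprintf("gene-%05d", seq_len(n_genes))
    panel_ids <- if (!is.null(panel) && length(panel$selected))
      panel$selected else utils::head(names(tm), 5)
    td <- run_stage("enrich", target_downregulation_test(
      mrna$matrix, mrna$meta$group, tm, panel_ids,
      sam_seed = stage_seed(config$seed, "enrich_sam")))
    jsonlite::write_json(
      list(counts = as.data.frame(td$counts), p_fisher = td$p_fisher,
           p_binomial = td$p_binomial, p0 = td$p0),
      out("enrich.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$enrich <- list(p_fisher = td$p_fisher,
                           p_binomial = td$p_binomial)
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
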