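#' Define a synthetic case/control simulation design
#'
#' The default design encodes the study conditions the downstream analyses
#' assume: 20 cases and 20 controls profiled over 847 miRNA features, of
#' which 31 are planted as up-regulated biomarkers with log2 fold changes
#' drawn uniformly from \[0.5, 1\] (linear fold changes of about 1.4-2.0),
#' per-feature baseline log2 means uniform in \[4, 14\], Gaussian noise with
#' standard deviation 0.5 on the log2 scale, and four latent correlation
#' blocks of sizes 10, 8, 6 and 4 (pairwise r = 0.75) placed inside the
#' planted biomarkers so that the selected panel sub-stratifies into
#' correlated clusters.
#'
#' @param n_cases,n_controls biological sample counts per arm.
#' @param n_features number of miRNA features on the array.
#' @param n_de number of planted differentially expressed features (always
#'   the first `n_de` features).
#' @param de_direction `"up"` (cases shifted up), `"down"`, or `"mixed"`
#'   (random sign per feature).
#' @param log2_fc_range range the planted log2 fold changes are drawn from.
#' @param baseline_mean_range range of per-feature baseline log2 means.
#' @param noise_sd_range range of per-feature noise standard deviations
#'   (log2 units); a degenerate range fixes the sd.
#' @param corr_blocks list of `c(block_size, latent_r)` pairs; blocks occupy
#'   consecutive features starting at feature 1.
#' @param probes_per_feature probes per feature for probe-level simulation.
#' @param n_antigenomic_per_gc anti-genomic background probes per GC class.
#' @param seed integer seed; every draw derives from it.
#' @return list of class `"sim_design"`.
#' @export
simulation_design <- function(n_cases = 20, n_controls = 20,
                              n_features = 847, n_de = 31,
                              de_direction = c("up", "down", "mixed"),
                              log2_fc_range = c(0.5, 1.0),
                              baseline_mean_range = c(4, 14),
                              noise_sd_range = c(0.5, 0.5),
                              corr_blocks = list(c(10, 0.75), c(8, 0.75),
                                                 c(6, 0.75), c(4, 0.75)),
                              probes_per_feature = 4,
                              n_antigenomic_per_gc = 20,
                              seed = 1) {
  de_direction <- match.arg(de_direction)
  stopifnot(n_cases >= 2, n_controls >= 2, n_features >= 1,
            n_de >= 0, n_de <= n_features,
            length(log2_fc_range) == 2, diff(log2_fc_range) >= 0,
            length(baseline_mean_range) == 2, diff(baseline_mean_range) >= 0,
            length(noise_sd_range) == 2, diff(noise_sd_range) >= 0,
            min(noise_sd_range) >= 0, probes_per_feature >= 1,
            n_antigenomic_per_gc >= 1)
  sizes <- vapply(corr_blocks, `[`, numeric(1), 1)
  rs    <- vapply(corr_blocks, `[`, numeric(1), 2)
  stopifnot(sum(sizes) <= n_features, all(sizes >= 2),
            all(rs >= 0), all(rs < 1))
  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_features = n_features,
    n_de = n_de, de_direction = de_direction, log2_fc_range = log2_fc_range,
    baseline_mean_range = baseline_mean_range,
    noise_sd_range = noise_sd_range, corr_blocks = corr_blocks,
    probes_per_feature = probes_per_feature,
    n_antigenomic_per_gc = n_antigenomic_per_gc, seed = seed),
    class = "sim_design")
}

#' Sample metadata implied by a design
#' @param design a [simulation_design()].
#' @param fraction blood fraction label for all samples.
#' @return sample table data.frame (cases `p01..`, controls `c01..`).
#' @export
design_sample_table <- function(design, fraction = "platelet") {
  stopifnot(inherits(design, "sim_design"), fraction %in% FRACTIONS)
  data.frame(
    sample_id = c(sprintf("p%02d", seq_len(design$n_cases)),
                  sprintf("c%02d", seq_len(design$n_controls))),
    group = rep(c("case", "control"), c(design$n_cases, design$n_controls)),
    fraction = fraction,
    replicate_of = NA_character_,
    stringsAsFactors = FALSE)
}

#' Simulate a feature-level log2 expression matrix with planted truth
#'
#' Each value is baseline + group shift (planted log2 FC, applied to cases
#' for `"up"`) + block latent factor + independent Gaussian noise. A block
#' with pairwise correlation rho contributes a shared standard-normal factor
#' loaded at `sqrt(rho) * sigma_f` with idiosyncratic noise sd
#' `sqrt(1 - rho) * sigma_f`, so each feature keeps total sd `sigma_f` and
#' every within-block pair has correlation rho in expectation.
#'
#' @param design a [simulation_design()].
#' @param fraction fraction label for the generated samples.
#' @return list: `matrix` (log2, features x samples), `meta` (sample table),
#'   `truth` (data.frame: feature_id, is_de, log2_fc, fold_change, block).
#' @export
simulate_feature_matrix <- function(design, fraction = "platelet") {
  stopifnot(inherits(design, "sim_design"))
  meta <- design_sample_table(design, fraction)
  p <- design$n_features
  n <- nrow(meta)
  feats <- sprintf("mir-%04d", seq_len(p))
  is_case <- meta$group == "case"

  with_seed(stage_seed(design$seed, "feature_matrix"), {
    baseline <- stats::runif(p, design$baseline_mean_range[1],
                             design$baseline_mean_range[2])
    sigma <- stats::runif(p, design$noise_sd_range[1],
                          design$noise_sd_range[2])
    lfc <- numeric(p)
    if (design$n_de > 0) {
      mag <- stats::runif(design$n_de, design$log2_fc_range[1],
                          design$log2_fc_range[2])
      sgn <- switch(design$de_direction,
                    up = 1,
                    down = -1,
                    mixed = sample(c(-1, 1), design$n_de, replace = TRUE))
      lfc[seq_len(design$n_de)] <- sgn * mag
    }
    block <- rep(NA_integer_, p)
    at <- 1L
    for (b in seq_along(design$corr_blocks)) {
      sz <- design$corr_blocks[[b]][1]
      block[at:(at + sz - 1L)] <- b
      at <- at + as.integer(sz)
    }

    x <- matrix(baseline, p, n) +
      outer(lfc, as.numeric(is_case))
    load <- rep(0, p)
    for (b in seq_along(design$corr_blocks)) {
      rho <- design$corr_blocks[[b]][2]
      idx <- which(block == b)
      z <- stats::rnorm(n)
      x[idx, ] <- x[idx, ] + sqrt(rho) * sigma[idx] %o% z
      load[idx] <- rho
    }
    x <- x + matrix(stats::rnorm(p * n), p, n) * sqrt(1 - load) * sigma
    dimnames(x) <- list(feats, meta$sample_id)

    truth <- data.frame(
      feature_id = feats,
      is_de = lfc != 0,
      log2_fc = lfc,
      fold_change = 2^lfc,
      block = block,
      stringsAsFactors = FALSE)
    list(matrix = x, meta = meta, truth = truth)
  })
}

#' Simulate a probe-level intensity table from a design
#'
#' Probe intensities are `2^(feature log2 value + affinity offset)` plus a
#' GC-class-dependent additive background and optional linear-scale noise;
#' anti-genomic probes carry background (plus noise) only. Probe affinity
#' offsets are drawn once per probe from `Normal(0, affinity_sd)` in log2
#' units, which median summarization removes. With `affinity_sd = 0`,
#' `probe_noise_sd = 0` and a zero background the construction is exactly
#' invertible by the preprocessing chain.
#'
#' @param design a [simulation_design()].
#' @param fraction fraction label.
#' @param gc_levels integer GC counts probes are assigned to (uniformly).
#' @param background_per_gc either a single number applied to every GC class
#'   or a function of gc_count returning the additive linear background.
#' @param affinity_sd sd of per-probe log2 affinity offsets.
#' @param probe_noise_sd sd of additive linear-scale probe noise.
#' @return list: `probes` (probe data.frame), `meta`, `truth`, and `feature`
#'   (the underlying feature-level log2 matrix).
#' @export
simulate_probe_matrix <- function(design, fraction = "platelet",
                                  gc_levels = 6:14,
                                  background_per_gc = function(gc) 8 + 2 * gc,
                                  affinity_sd = 0.25,
                                  probe_noise_sd = 0) {
  stopifnot(inherits(design, "sim_design"), design$probes_per_feature >= 1)
  fm <- simulate_feature_matrix(design, fraction)
  bg_of <- if (is.function(background_per_gc)) background_per_gc
           else function(gc) rep(background_per_gc, length(gc))

  with_seed(stage_seed(design$seed, "probe_matrix"), {
    p <- design$n_features
    k <- design$probes_per_feature
    n <- ncol(fm$matrix)
    probe_feat <- rep(seq_len(p), each = k)
    gc <- sample(gc_levels, p * k, replace = TRUE)
    aff <- stats::rnorm(p * k, 0, affinity_sd)
    sig <- 2^(fm$matrix[probe_feat, , drop = FALSE] + aff)
    bg <- bg_of(gc)
    vals <- sig + bg
    if (probe_noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, probe_noise_sd),
                            nrow(vals), ncol(vals))
    vals <- pmax(vals, 0)

    gc_used <- sort(unique(gc))
    ag_gc <- rep(gc_used, each = design$n_antigenomic_per_gc)
    ag <- matrix(rep(bg_of(ag_gc), n), length(ag_gc), n)
    if (probe_noise_sd > 0)
      ag <- ag + matrix(stats::rnorm(length(ag), 0, probe_noise_sd),
                        nrow(ag), ncol(ag))
    ag <- pmax(ag, 0)

    probes <- data.frame(
      probe_id = c(sprintf("probe-%06d", seq_len(p * k)),
                   sprintf("antigen-%05d", seq_along(ag_gc))),
      feature_id = c(rownames(fm$matrix)[probe_feat],
                     rep("", length(ag_gc))),
      gc_count = c(gc, ag_gc),
      is_antigenomic = rep(c(FALSE, TRUE), c(p * k, length(ag_gc))),
      stringsAsFactors = FALSE)
    intens <- rbind(vals, ag)
    colnames(intens) <- colnames(fm$matrix)
    probes <- cbind(probes, as.data.frame(intens, check.names = FALSE))
    rownames(probes) <- NULL
    validate_probe_matrix(probes)
    list(probes = probes, meta = fm$meta, truth = fm$truth,
         feature = fm$matrix)
  })
}

#' Simulate a miRNA-to-target-gene map
#'
#' Each miRNA targets a uniform random subset of the gene universe, so two
#' miRNAs' target sets overlap by about `targets_per_mirna^2 / n_genes` genes
#' in expectation.
#'
#' @param n_mirnas number of miRNAs (ids match the feature generator's).
#' @param n_genes size of the gene universe.
#' @param targets_per_mirna targets drawn per miRNA (without replacement).
#' @param seed integer seed.
#' @return named list: miRNA id -> character vector of gene ids.
#' @export
simulate_target_map <- function(n_mirnas, n_genes, targets_per_mirna, seed = 1) {
  stopifnot(n_mirnas >= 1, n_genes >= 1, targets_per_mirna >= 0,
            targets_per_mirna <= n_genes)
  genes <- sprintf("gene-%05d", seq_len(n_genes))
  with_seed(stage_seed(seed, "target_map"), {
    tm <- lapply(seq_len(n_mirnas), function(i)
      sort(sample(genes, targets_per_mirna)))
    names(tm) <- sprintf("mir-%04d", seq_len(n_mirnas))
    tm
  })
}
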