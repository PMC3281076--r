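#' Consensus (stability) selection parameters
#'
#' Defaults mirror the derivation protocol: 100 resampling iterations, each
#' drawing 18 of 20 cases and 18 of 20 controls (a randomized 9:1 split) and
#' running SAM at FDR 1%; features called in at least 90% of iterations are
#' selected as biomarkers.
#'
#' @param n_iterations resampling iterations.
#' @param subset_cases,subset_controls per-class subsample sizes drawn
#'   without replacement each iteration.
#' @param frequency_threshold selection frequency cut (in (0, 1\]).
#' @param threshold_comparator `">="` (the operational "no less than 90%"
#'   reading, default) or `">"`.
#' @param sam_params a [sam_params()] used for every iteration.
#' @param seed master seed; per-iteration subsample and permutation streams
#'   derive from it.
#' @return list of class `"consensus_params"`.
#' @export
consensus_params <- function(n_iterations = 100, subset_cases = 18,
                             subset_controls = 18,
                             frequency_threshold = 0.9,
                             threshold_comparator = c(">=", ">"),
                             sam_params = circumir::sam_params(
                               n_permutations = 200),
                             seed = 1) {
  threshold_comparator <- match.arg(threshold_comparator)
  stopifnot(n_iterations >= 1, subset_cases >= 2, subset_controls >= 2,
            frequency_threshold > 0, frequency_threshold <= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 subset_cases = as.integer(subset_cases),
                 subset_controls = as.integer(subset_controls),
                 frequency_threshold = frequency_threshold,
                 threshold_comparator = threshold_comparator,
                 sam_params = sam_params, seed = seed),
            class = "consensus_params")
}

#' Resampling-consensus biomarker derivation
#'
#' Repeats SAM on random without-replacement case/control subsamples and
#' accumulates, per feature, the frequency of being called, the mean score
#' and mean fold change over calling iterations, and the call direction
#' (`"mixed"`, logged prominently, if a feature is called up in some
#' iterations and down in others). Features whose frequency passes the
#' threshold are the consensus panel.
#'
#' Subsamples are drawn from the class-wise sorted sample ids, so the result
#' does not depend on the column order of `m`.
#'
#' @param m log2 expression matrix (features x samples).
#' @param meta sample table (replicates must already be averaged).
#' @param params a [consensus_params()].
#' @return object of class `"consensus_panel"`: list with `table`
#'   (data.frame: feature_id, frequency, mean_score, mean_fold_change,
#'   direction, selected), `n_iterations`, `threshold`, `selected`
#'   (character vector of selected feature ids).
#' @export
derive_consensus <- function(m, meta, params = consensus_params()) {
  validate_expr_matrix(m)
  meta <- validate_sample_table(meta)
  stopifnot(inherits(params, "consensus_params"),
            all(meta$sample_id %in% colnames(m)))
  cases <- sort(meta$sample_id[meta$group == "case"])
  ctrls <- sort(meta$sample_id[meta$group == "control"])
  if (length(cases) < params$subset_cases ||
      length(ctrls) < params$subset_controls)
    stop("subset sizes exceed available samples per class")

  p <- nrow(m)
  ncalled <- integer(p)
  sum_score <- numeric(p)
  sum_fc <- numeric(p)
  up_called <- integer(p)
  dn_called <- integer(p)

  for (it in seq_len(params$n_iterations)) {
    sub <- with_seed(stage_seed(params$seed, paste0("consensus_draw:", it)), {
      c(sample(cases, params$subset_cases),
        sample(ctrls, params$subset_controls))
    })
    sp <- params$sam_params
    sp$seed <- stage_seed(params$seed, paste0("consensus_sam:", it))
    labels <- ifelse(sub %in% cases, "case", "control")
    res <- sam_calibrate(m[, sub, drop = FALSE], labels, sp,
                         compute_q = FALSE)
    tab <- res$table[match(rownames(m), res$table$feature_id), ]
    hit <- tab$called
    ncalled <- ncalled + hit
    sum_score[hit] <- sum_score[hit] + tab$score[hit]
    sum_fc[hit] <- sum_fc[hit] + tab$fold_change[hit]
    up_called <- up_called + (hit & tab$direction %in% "up")
    dn_called <- dn_called + (hit & tab$direction %in% "down")
  }

  freq <- ncalled / params$n_iterations
  direction <- rep(NA_character_, p)
  direction[up_called > 0 & dn_called == 0] <- "up"
  direction[dn_called > 0 & up_called == 0] <- "down"
  mixed <- up_called > 0 & dn_called > 0
  direction[mixed] <- "mixed"
  if (any(mixed))
    message("direction-mixed feature(s) across iterations: ",
            paste(rownames(m)[mixed], collapse = ", "))
  selected <- if (params$threshold_comparator == ">=")
    freq >= params$frequency_threshold else freq > params$frequency_threshold

  tab <- data.frame(
    feature_id = rownames(m),
    frequency = freq,
    mean_score = ifelse(ncalled > 0, sum_score / pmax(ncalled, 1), NA_real_),
    mean_fold_change = ifelse(ncalled > 0, sum_fc / pmax(ncalled, 1),
                              NA_real_),
    direction = direction,
    selected = selected,
    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 n_iterations = params$n_iterations,
                 threshold = params$frequency_threshold,
                 selected = tab$feature_id[selected]),
            class = "consensus_panel")
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat("Consensus panel: ", length(x$selected), " / ", nrow(x$table),
      " features at frequency >= ", x$threshold, " over ", x$n_iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' Row-concatenate per-fraction expression matrices
#'
#' Builds the "union of fractions" matrix by stacking fraction matrices over
#' the same samples, prefixing feature ids with a fraction tag (`pl:`,
#' `mv:`, `pb:`) so shared miRNA names cannot collide.
#'
#' @param m_by_fraction named list of expression matrices, names in
#'   `platelet`, `microvesicle`, `pbmc`; all must share the same sample set
#'   (per-subject pairing).
#' @return stacked log2 matrix with prefixed feature ids, columns in the
#'   first matrix's sample order.
#' @export
combine_fractions <- function(m_by_fraction) {
  stopifnot(is.list(m_by_fraction), length(m_by_fraction) >= 1,
            !is.null(names(m_by_fraction)))
  bad <- setdiff(names(m_by_fraction), FRACTIONS)
  if (length(bad)) stop("unknown fraction label(s): ",
                        paste(bad, collapse = ", "))
  prefix <- c(platelet = "pl", microvesicle = "mv", pbmc = "pb")
  ref <- colnames(m_by_fraction[[1]])
  pieces <- lapply(names(m_by_fraction), function(fr) {
    m <- m_by_fraction[[fr]]
    validate_expr_matrix(m)
    off <- c(setdiff(ref, colnames(m)), setdiff(colnames(m), ref))
    if (length(off))
      stop("fraction '", fr, "' sample mismatch: ",
           paste(unique(off), collapse = ", "))
    m <- m[, ref, drop = FALSE]
    rownames(m) <- paste0(prefix[[fr]], ":", rownames(m))
    m
  })
  do.call(rbind, pieces)
}

strip_fraction_prefix <- function(ids) sub("^(pl|mv|pb):", "", ids)

#' Pairwise overlap of consensus panels
#'
#' Fraction prefixes are stripped before comparison, so a feature selected
#' from the platelet matrix and from the combined matrix counts as shared.
#'
#' @param panels named list of `"consensus_panel"` objects (or character
#'   vectors of selected feature ids); at least two.
#' @return data.frame, one row per unordered pair: sizes, intersection
#'   count, set-difference counts, Jaccard index.
#' @export
panel_overlap <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 2, !is.null(names(panels)))
  sets <- lapply(panels, function(p) {
    ids <- if (inherits(p, "consensus_panel")) p$selected else as.character(p)
    unique(strip_fraction_prefix(ids))
  })
  prs <- utils::combn(names(sets), 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    i <- length(intersect(a, b)); u <- length(union(a, b))
    data.frame(panel_a = pr[1], panel_b = pr[2],
               size_a = length(a), size_b = length(b),
               intersection = i,
               only_a = length(setdiff(a, b)),
               only_b = length(setdiff(b, a)),
               jaccard = if (u > 0) i / u else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
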