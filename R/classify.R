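#' Nested Monte-Carlo cross-validation parameters
#'
#' Defaults mirror the evaluation protocol: 100 repetitions of a random
#' 18:2-per-class train/test split; inside each training set the consensus
#' selector runs on random 16-per-class subsets (SAM at FDR 1%, frequency
#' threshold 90%) to pick features, and an RBF-kernel soft-margin SVM
#' (cost 1, kernel width 1/number of selected features, features
#' standardized to training mean 0 / sd 1) is trained and applied to the
#' held-out samples. The protocol is described as 10-fold cross-validation
#' in the field but is operationally repeated Monte-Carlo splitting, which
#' is what this implements.
#'
#' @param n_repetitions outer repetitions.
#' @param train_cases,train_controls per-class training-set sizes (the
#'   remaining samples form the test set).
#' @param inner_cases,inner_controls per-class subset sizes for the in-fold
#'   consensus selector.
#' @param inner_consensus_iterations resampling iterations inside each fold
#'   (default 20; the derivation-faithful 100 costs ~5x runtime).
#' @param inner_sam_params [sam_params()] for the in-fold SAM runs.
#' @param frequency_threshold in-fold consensus frequency cut.
#' @param kernel_gamma RBF width; `NULL` (default) means the reciprocal of
#'   the number of selected features.
#' @param cost soft-margin cost parameter.
#' @param standardize standardize selected features from training
#'   statistics before fitting (default `TRUE`).
#' @param seed master seed.
#' @return list of class `"eval_params"`.
#' @export
eval_params <- function(n_repetitions = 100, train_cases = 18,
                        train_controls = 18, inner_cases = 16,
                        inner_controls = 16,
                        inner_consensus_iterations = 20,
                        inner_sam_params = sam_params(n_permutations = 100),
                        frequency_threshold = 0.9,
                        kernel_gamma = NULL, cost = 1,
                        standardize = TRUE, seed = 1) {
  stopifnot(n_repetitions >= 1, inner_cases < train_cases,
            inner_controls < train_controls, inner_cases >= 2,
            inner_controls >= 2, cost > 0,
            inner_consensus_iterations >= 1)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 train_cases = as.integer(train_cases),
                 train_controls = as.integer(train_controls),
                 inner_cases = as.integer(inner_cases),
                 inner_controls = as.integer(inner_controls),
                 inner_consensus_iterations =
                   as.integer(inner_consensus_iterations),
                 inner_sam_params = inner_sam_params,
                 frequency_threshold = frequency_threshold,
                 kernel_gamma = kernel_gamma, cost = cost,
                 standardize = standardize, seed = seed),
            class = "eval_params")
}

#' Performance measures from an aggregated confusion matrix
#'
#' Cases are the positive class. Sensitivity is `1 - FNR`, specificity is
#' `1 - FPR`, and accuracy is `(tp + tn) / total`.
#'
#' @param tp,fp,tn,fn aggregated confusion counts.
#' @return named list: accuracy, sensitivity, specificity, ppv, npv, fpr,
#'   fnr.
#' @export
perf_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
       fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_)
}

# In-fold feature selection: consensus over random inner subsets of the
# training samples only. Falls back to a single SAM run on the full
# training split if the consensus set is empty.
select_in_fold <- function(m_train, meta_train, params, rep_seed) {
  cp <- consensus_params(
    n_iterations = params$inner_consensus_iterations,
    subset_cases = params$inner_cases,
    subset_controls = params$inner_controls,
    frequency_threshold = params$frequency_threshold,
    sam_params = params$inner_sam_params,
    seed = stage_seed(rep_seed, "inner_consensus"))
  panel <- derive_consensus(m_train, meta_train, cp)
  feats <- panel$selected
  fallback <- "none"
  if (!length(feats)) {
    sp <- params$inner_sam_params
    sp$seed <- stage_seed(rep_seed, "fallback_sam")
    res <- sam_calibrate(m_train, meta_train$group, sp, compute_q = FALSE)
    feats <- res$table$feature_id[res$table$called]
    fallback <- if (length(feats)) "single_sam" else "majority_class"
  }
  list(features = feats, fallback = fallback)
}

#' Nested Monte-Carlo cross-validated classifier evaluation
#'
#' Per repetition: draw a training set and a disjoint test set (everything
#' not drawn), select features by in-fold consensus using training samples
#' only, standardize the selected features to training mean/sd, fit an
#' RBF-kernel SVM, predict the test samples, and accumulate the confusion
#' counts and per-sample misclassification tallies. Metrics are computed
#' from the summed confusion matrix, matching the aggregated-confusion
#' protocol.
#'
#' @param m log2 expression matrix (features x samples).
#' @param meta sample table.
#' @param params an [eval_params()].
#' @return object of class `"eval_result"`: list with `confusion`
#'   (tp/fp/tn/fn, n_repetitions), `metrics` ([perf_metrics()]),
#'   `per_sample` (data.frame: sample_id, group, times_tested,
#'   times_misclassified, rate), `panels` (list of per-repetition selected
#'   feature vectors), `fallbacks` (per-repetition fallback labels).
#' @export
evaluate_classifier <- function(m, meta, params = eval_params()) {
  validate_expr_matrix(m)
  meta <- validate_sample_table(meta)
  stopifnot(inherits(params, "eval_params"),
            all(meta$sample_id %in% colnames(m)))
  cases <- sort(meta$sample_id[meta$group == "case"])
  ctrls <- sort(meta$sample_id[meta$group == "control"])
  if (length(cases) <= params$train_cases ||
      length(ctrls) <= params$train_controls)
    stop("training sizes must leave at least one test sample per class")

  tp <- fp <- tn <- fn <- 0L
  tested <- misclass <- stats::setNames(integer(nrow(meta)), meta$sample_id)
  panels <- vector("list", params$n_repetitions)
  fallbacks <- character(params$n_repetitions)

  for (r in seq_len(params$n_repetitions)) {
    rep_seed <- stage_seed(params$seed, paste0("eval_rep:", r))
    split <- with_seed(stage_seed(rep_seed, "split"), {
      list(train = c(sample(cases, params$train_cases),
                     sample(ctrls, params$train_controls)))
    })
    train_ids <- split$train
    test_ids <- setdiff(c(cases, ctrls), train_ids)
    stopifnot(length(intersect(train_ids, test_ids)) == 0)

    meta_train <- meta[match(train_ids, meta$sample_id), , drop = FALSE]
    sel <- select_in_fold(m[, train_ids, drop = FALSE], meta_train,
                          params, rep_seed)
    panels[[r]] <- sel$features
    fallbacks[r] <- sel$fallback

    truth <- ifelse(test_ids %in% cases, "case", "control")
    if (sel$fallback == "majority_class") {
      maj <- names(which.max(table(factor(meta_train$group, GROUPS))))
      if (sum(meta_train$group == "case") ==
          sum(meta_train$group == "control")) maj <- "control"
      pred <- rep(maj, length(test_ids))
    } else {
      xtr <- t(m[sel$features, train_ids, drop = FALSE])
      xte <- t(m[sel$features, test_ids, drop = FALSE])
      if (params$standardize) {
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        xtr <- scale(xtr, mu, sdv)
        xte <- scale(xte, mu, sdv)
      }
      ytr <- factor(ifelse(train_ids %in% cases, "case", "control"), GROUPS)
      gamma <- if (is.null(params$kernel_gamma)) 1 / ncol(xtr)
               else params$kernel_gamma
      fit <- e1071::svm(xtr, ytr, kernel = "radial", gamma = gamma,
                        cost = params$cost, scale = FALSE)
      pred <- as.character(stats::predict(fit, xte))
    }

    tp <- tp + sum(pred == "case" & truth == "case")
    fn <- fn + sum(pred == "control" & truth == "case")
    tn <- tn + sum(pred == "control" & truth == "control")
    fp <- fp + sum(pred == "case" & truth == "control")
    tested[test_ids] <- tested[test_ids] + 1L
    wrong <- test_ids[pred != truth]
    misclass[wrong] <- misclass[wrong] + 1L
  }

  per_sample <- data.frame(
    sample_id = meta$sample_id,
    group = meta$group,
    times_tested = unname(tested[meta$sample_id]),
    times_misclassified = unname(misclass[meta$sample_id]),
    rate = ifelse(tested[meta$sample_id] > 0,
                  unname(misclass[meta$sample_id] / tested[meta$sample_id]),
                  0),
    stringsAsFactors = FALSE)
  per_sample <- per_sample[order(-per_sample$rate, per_sample$sample_id), ]
  rownames(per_sample) <- NULL

  structure(list(
    confusion = list(tp = tp, fp = fp, tn = tn, fn = fn,
                     n_repetitions = params$n_repetitions),
    metrics = perf_metrics(tp, fp, tn, fn),
    per_sample = per_sample,
    panels = panels,
    fallbacks = fallbacks),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cf <- x$confusion
  cat(sprintf(
    "Nested CV over %d repetitions: tp=%d fp=%d tn=%d fn=%d\n",
    cf$n_repetitions, cf$tp, cf$fp, cf$tn, cf$fn))
  cat(sprintf(
    "accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    100 * x$metrics$accuracy, 100 * x$metrics$sensitivity,
    100 * x$metrics$specificity))
  invisible(x)
}

#' Per-sample misclassification report
#'
#' @param ev an `"eval_result"`.
#' @return data.frame sorted by descending misclassification rate:
#'   sample_id, group, times_tested, times_misclassified, rate.
#' @export
misclassification_report <- function(ev) {
  stopifnot(inherits(ev, "eval_result"))
  ev$per_sample
}
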