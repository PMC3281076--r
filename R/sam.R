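#' SAM parameters
#'
#' @param fdr_target target false discovery rate for calling features
#'   (default 0.01, i.e. the 1% threshold used for biomarker derivation).
#' @param n_permutations cap on label permutations; when the permutation
#'   space is at most this size every distinct relabeling is used (exact
#'   null), otherwise permutations are sampled uniformly without
#'   replacement.
#' @param s0_mode `"auto_percentile"` tunes the fudge factor from the data;
#'   `"fixed"` uses `s0_value`.
#' @param s0_value fixed fudge factor (required when `s0_mode = "fixed"`).
#' @param seed integer seed for the permutation stream.
#' @return list of class `"sam_params"`.
#' @export
sam_params <- function(fdr_target = 0.01, n_permutations = 1000,
                       s0_mode = c("auto_percentile", "fixed"),
                       s0_value = NULL, seed = 1) {
  s0_mode <- match.arg(s0_mode)
  stopifnot(fdr_target > 0, fdr_target < 1, n_permutations >= 1)
  if (s0_mode == "fixed" && (is.null(s0_value) || s0_value < 0))
    stop("s0_mode = 'fixed' requires a nonnegative s0_value")
  structure(list(fdr_target = fdr_target,
                 n_permutations = as.integer(n_permutations),
                 s0_mode = s0_mode, s0_value = s0_value, seed = seed),
            class = "sam_params")
}

as_case <- function(labels, n) {
  if (is.logical(labels)) {
    stopifnot(length(labels) == n)
    return(labels)
  }
  stopifnot(length(labels) == n, all(labels %in% GROUPS))
  labels == "case"
}

# Pooled standard error s_i per feature (two-class unpaired).
pooled_se <- function(m, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  x1 <- m[, is_case, drop = FALSE]; x2 <- m[, !is_case, drop = FALSE]
  ss1 <- rowSums((x1 - rowMeans(x1))^2)
  ss2 <- rowSums((x2 - rowMeans(x2))^2)
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

#' SAM modified t-scores
#'
#' `d_i = (mean_case - mean_control) / (s_i + s0)` with `s_i` the pooled
#' standard error over the two classes. The constant `s0` damps the scores
#' of low-variance features.
#'
#' @param m log2 expression matrix (features x samples).
#' @param labels per-column class labels (`"case"`/`"control"` or logical
#'   case indicator).
#' @param s0 fudge factor (>= 0).
#' @return named numeric vector of scores.
#' @export
sam_scores <- function(m, labels, s0 = 0) {
  validate_expr_matrix(m)
  is_case <- as_case(labels, ncol(m))
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("each class needs at least 2 samples")
  diff <- rowMeans(m[, is_case, drop = FALSE]) -
          rowMeans(m[, !is_case, drop = FALSE])
  d <- diff / (pooled_se(m, is_case) + s0)
  d[diff == 0] <- 0  # zero numerator wins over a zero denominator
  names(d) <- rownames(m)
  d
}

#' Linear fold change from log2 group means
#'
#' `FC = 2^(mean_case - mean_control)`: the anti-logged difference of log2
#' group means, i.e. the ratio of (geometric) mean intensities of cases over
#' controls.
#'
#' @inheritParams sam_scores
#' @return named numeric vector of positive fold changes.
#' @export
fold_change <- function(m, labels) {
  validate_expr_matrix(m)
  is_case <- as_case(labels, ncol(m))
  fc <- 2^(rowMeans(m[, is_case, drop = FALSE]) -
           rowMeans(m[, !is_case, drop = FALSE]))
  names(fc) <- rownames(m)
  fc
}

#' Tune the SAM fudge factor s0
#'
#' Standard SAM tuning: candidates are the percentiles 0, 5, ..., 95 of the
#' pooled standard errors `s_i`; for each candidate the scores are
#' recomputed and the coefficient of variation of the median absolute
#' deviation of the scores across `s_i`-quantile windows is measured; the
#' candidate minimizing that coefficient wins, ties going to the smallest
#' percentile. Deterministic given the input.
#'
#' @inheritParams sam_scores
#' @return the chosen s0 (>= 0).
#' @export
choose_s0 <- function(m, labels) {
  validate_expr_matrix(m)
  is_case <- as_case(labels, ncol(m))
  si <- pooled_se(m, is_case)
  if (all(si == 0)) {
    warning("all per-feature standard errors are zero; using s0 = 1e-8")
    return(1e-8)
  }
  diff <- rowMeans(m[, is_case, drop = FALSE]) -
          rowMeans(m[, !is_case, drop = FALSE])
  p <- length(si)
  alphas <- seq(0, 0.95, by = 0.05)
  cands <- stats::quantile(si, alphas, names = FALSE)
  nb <- min(100L, max(2L, p %/% 10L))
  breaks <- unique(stats::quantile(si, seq(0, 1, length.out = nb + 1),
                                   names = FALSE))
  if (length(breaks) < 2) breaks <- range(si) + c(-1e-12, 1e-12)
  bins <- cut(si, breaks, include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    dd <- diff / (si + s0)
    v <- tapply(dd, bins, stats::mad)
    v <- v[!is.na(v)]
    mu <- mean(v)
    if (!is.finite(mu) || mu <= 0) return(Inf)
    stats::sd(v) / mu
  }, numeric(1))
  cands[which.min(cv)]
}

# Distinct case/control relabelings as an n x B 0/1 indicator matrix.
# All relabelings when the space is small enough, else uniform sampling
# without replacement. Deterministic given the seed.
sample_label_perms <- function(n, n1, n_max, seed) {
  total <- choose(n, n1)
  if (total <= n_max) {
    combos <- utils::combn(n, n1, simplify = FALSE)
  } else {
    combos <- with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", n_max)
      got <- 0L
      while (got < n_max) {
        s <- sort(sample.int(n, n1))
        k <- paste(s, collapse = ",")
        if (is.null(seen[[k]])) {
          assign(k, TRUE, envir = seen)
          got <- got + 1L
          out[[got]] <- s
        }
      }
      out
    })
  }
  ind <- matrix(0, n, length(combos))
  for (b in seq_along(combos)) ind[combos[[b]], b] <- 1
  ind
}

# Modified t-scores for every relabeling at once (two matrix products).
perm_scores <- function(m, case_ind, s0) {
  n <- nrow(case_ind)
  n1 <- sum(case_ind[, 1]); n2 <- n - n1
  s1 <- m %*% case_ind
  q1 <- (m * m) %*% case_ind
  tot <- rowSums(m)
  qt <- rowSums(m * m)
  mu1 <- s1 / n1
  mu2 <- (tot - s1) / n2
  ss1 <- pmax(q1 - s1^2 / n1, 0)
  ss2 <- pmax((qt - q1) - (tot - s1)^2 / n2, 0)
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n - 2))
  d <- (mu1 - mu2) / (si + s0)
  d[mu1 == mu2] <- 0
  d
}

#' Two-class unpaired SAM with permutation-estimated FDR
#'
#' Computes observed modified t-scores, builds the permutation null from
#' distinct label relabelings, estimates the null proportion pi0 from the
#' share of permuted scores inside the interquartile range of the observed
#' scores, and scans delta thresholds on the sorted observed-vs-expected
#' score differences: for each delta the up/down cut points are the observed
#' scores at the first crossings beyond the center, the estimated FDR is
#' `pi0 * median permuted count beyond the cuts / max(1, called)`, and the
#' smallest delta with estimated FDR at or below the target defines the
#' called set. Per-feature q-values are the minimum estimated FDR over the
#' deltas at which the feature is called (clamped to \[0, 1\]); q-values of
#' exactly 0 mean the score was more extreme than every permuted score and
#' are flagged, not claimed to be true zeros.
#'
#' Columns are internally reordered to a canonical (class, sample-id) order
#' so results are invariant to input column order.
#'
#' @inheritParams sam_scores
#' @param params a [sam_params()].
#' @param compute_q compute per-feature q-values (skippable for speed inside
#'   resampling loops where only the called set matters).
#' @return object of class `"sam_result"`: list with `table` (data.frame:
#'   feature_id, score, fold_change, q_value, called, direction),
#'   `s0`, `delta`, `pi0`, `expected_order_scores`, `n_permutations_used`,
#'   `fdr_target`.
#' @export
sam_calibrate <- function(m, labels, params = sam_params(),
                          compute_q = TRUE) {
  validate_expr_matrix(m)
  stopifnot(inherits(params, "sam_params"))
  is_case <- as_case(labels, ncol(m))
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples")
  if (params$n_permutations < 50)
    warning("fewer than 50 permutations: FDR estimate will be unstable")
  ord_cols <- order(!is_case, colnames(m))
  m <- m[, ord_cols, drop = FALSE]
  is_case <- is_case[ord_cols]

  s0 <- if (params$s0_mode == "fixed") params$s0_value
        else choose_s0(m, is_case)
  d <- sam_scores(m, is_case, s0)
  fc <- fold_change(m, is_case)
  p <- length(d)

  ind <- sample_label_perms(ncol(m), n1, params$n_permutations,
                            stage_seed(params$seed, "sam_perms"))
  B <- ncol(ind)
  D <- perm_scores(m, ind, s0)
  Dsort <- apply(D, 2, sort)
  dbar <- rowMeans(Dsort)
  ord <- order(d)
  ds <- d[ord]
  diffs <- ds - dbar

  qs <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(D >= qs[1] & D <= qs[2]) / (0.5 * length(D)))

  # first index with positive expected score marks the up side's start;
  # the down side ends at the last negative expected score
  c_up <- if (any(dbar > 0)) which(dbar > 0)[1] else p + 1L
  c_dn <- if (any(dbar < 0)) max(which(dbar < 0)) else 0L

  grid <- sort(unique(abs(diffs)))
  grid <- grid[grid > 0]
  if (length(grid) > 160)
    grid <- grid[unique(round(seq(1, length(grid), length.out = 160)))]
  G <- length(grid)
  tol <- 1e-9 * max(1, max(abs(ds)))

  cutup <- rep(Inf, G); cutlow <- rep(-Inf, G)
  ncall <- integer(G)
  if (G > 0) {
    up_diffs <- if (c_up <= p) diffs[c_up:p] else numeric(0)
    dn_diffs <- if (c_dn >= 1) rev(diffs[1:c_dn]) else numeric(0)
    for (g in seq_len(G)) {
      j <- which(up_diffs >= grid[g])[1]
      if (!is.na(j)) cutup[g] <- ds[c_up + j - 1L]
      j <- which(dn_diffs <= -grid[g])[1]
      if (!is.na(j)) cutlow[g] <- ds[c_dn - j + 1L]
      ncall[g] <- sum(d >= cutup[g] - tol) + sum(d <= cutlow[g] + tol)
    }
    # median over permutations of the count of permuted scores beyond cuts
    counts <- vapply(seq_len(B), function(b) {
      col <- Dsort[, b]
      (p - findInterval(cutup - tol, col)) + findInterval(cutlow + tol, col)
    }, numeric(G))
    counts <- matrix(counts, nrow = G)
    med_false <- apply(counts, 1, stats::median)
    fdr_at <- pmin(1, pi0 * med_false / pmax(1, ncall))
  } else {
    fdr_at <- numeric(0)
  }

  g_star <- which(fdr_at <= params$fdr_target & ncall > 0)[1]
  if (is.na(g_star)) {
    delta <- Inf
    called <- rep(FALSE, p)
  } else {
    delta <- grid[g_star]
    called <- d >= cutup[g_star] - tol | d <= cutlow[g_star] + tol
  }
  direction <- ifelse(called, ifelse(d > 0, "up", "down"), NA_character_)

  q_value <- rep(NA_real_, p)
  if (compute_q && G > 0) {
    cmin <- cummin(fdr_at)
    q_value <- vapply(d, function(di) {
      gmax_up <- findInterval(di + tol, cutup)         # cutup nondecreasing
      gmax_dn <- sum(cutlow >= di - tol)               # cutlow nonincreasing
      gmax <- max(gmax_up, gmax_dn)
      if (gmax >= 1) cmin[gmax] else 1
    }, numeric(1))
    q_value <- pmin(pmax(q_value, 0), 1)
  } else if (compute_q) {
    q_value <- rep(1, p)
  }

  structure(list(
    table = data.frame(
      feature_id = names(d), score = unname(d), fold_change = unname(fc),
      q_value = q_value, called = unname(called), direction = direction,
      stringsAsFactors = FALSE),
    s0 = s0, delta = delta, pi0 = pi0,
    expected_order_scores = dbar,
    n_permutations_used = B,
    fdr_target = params$fdr_target),
    class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM two-class result: ", nrow(x$table), " features, ",
      sum(x$table$called), " called at FDR <= ", x$fdr_target,
      " (s0 = ", signif(x$s0, 3), ", delta = ", signif(x$delta, 3),
      ", pi0 = ", signif(x$pi0, 3), ", ", x$n_permutations_used,
      " permutations)\n", sep = "")
  invisible(x)
}
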