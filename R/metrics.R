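# Source-localization quality measures. All of them consume the
# non-thresholded estimate: binarization happens only on the simulated truth
# (AUC/F1 labels) or not at all (EMD, DLE).

#' Dipole localization error
#'
#' Mean, over the simulated patch centers, of the Euclidean distance to the
#' nearest local maximum of `|j_est|` over the adjacency graph (a generator
#' is a local maximum when its absolute amplitude is >= that of every
#' neighbor and positive). A flat-positive estimate makes every generator a
#' local maximum; an all-zero estimate is an error.
#'
#' @param j_true unused except for validation symmetry (kept for a uniform
#'   metric signature); may be NULL.
#' @param j_est numeric S-vector estimate.
#' @param positions S x 3 generator coordinates (mm).
#' @param adjacency S x S neighbor matrix.
#' @param patch_centers integer vector of true patch-center indices.
#' @param symmetric if TRUE, also average the reverse direction (estimated
#'   peaks to nearest true center) and return the mean of both.
#' @return mean distance in mm.
#' @export
dle <- function(j_true, j_est, positions, adjacency, patch_centers,
                symmetric = FALSE) {
  x <- abs(j_est)
  if (max(x) == 0) stop("DLE undefined for an all-zero estimate")
  S <- length(x)
  is_max <- vapply(seq_len(S), function(i) {
    nb <- which(adjacency[i, ])
    x[i] > 0 && (length(nb) == 0 || all(x[i] >= x[nb]))
  }, logical(1))
  peaks <- which(is_max)
  if (length(peaks) == 0) peaks <- which.max(x)
  dmat <- function(from, to) {
    sqrt(outer(rowSums(positions[from, , drop = FALSE]^2),
               rowSums(positions[to, , drop = FALSE]^2), `+`) -
           2 * positions[from, , drop = FALSE] %*%
           t(positions[to, , drop = FALSE]))
  }
  fwd <- mean(apply(dmat(patch_centers, peaks), 1L, min))
  if (!symmetric) return(fwd)
  bwd <- mean(apply(dmat(peaks, patch_centers), 1L, min))
  (fwd + bwd) / 2
}

#' ROC area under the curve, in percent
#'
#' Scores `|j_est|` against the binarized truth `j_true != 0` with the
#' mid-rank (trapezoidal) tie convention; equals the rescaled Mann-Whitney U
#' statistic. 100 is reached only when every active generator outscores every
#' inactive one.
#'
#' @param j_true numeric S-vector with both zero and nonzero entries.
#' @param j_est numeric S-vector estimate (not thresholded).
#' @return AUC in `[0, 100]`.
#' @export
roc_auc <- function(j_true, j_est) {
  labels <- j_true != 0
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for single-class labels")
  r <- rank(abs(j_est), ties.method = "average")
  100 * (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score at the optimal ROC operating point, in percent
#'
#' Sweeps thresholds over the unique values of `|j_est|` (predict active when
#' `|j_est| >= threshold`), picks the operating point maximizing Youden's J
#' (TPR - FPR), and reports precision, recall and their harmonic mean
#' (`mean = "geometric"` switches to sqrt(P R)).
#'
#' @inheritParams roc_auc
#' @param mean `"harmonic"` (standard F1, default) or `"geometric"`.
#' @return list with `f1` (percent), `threshold`, `recall`, `precision`.
#' @export
f1_optimal <- function(j_true, j_est, mean = c("harmonic", "geometric")) {
  mean <- match.arg(mean)
  labels <- j_true != 0
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("F1 undefined for single-class labels")
  s <- abs(j_est)
  # thresholds in decreasing order, preceded by an "empty prediction"
  # corner so an uninformative scorer resolves to F1 = 0 rather than to the
  # all-positive corner (both have Youden's J = 0; ties break to the
  # highest threshold)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(s[labels] >= th) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(s[!labels] >= th) / n0, numeric(1))
  best <- which.max(tpr - fpr)
  th <- thr[best]
  tp <- sum(s[labels] >= th)
  fp <- sum(s[!labels] >= th)
  recall <- tp / n1
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else {
    if (mean == "harmonic") 2 * precision * recall / (precision + recall)
    else sqrt(precision * recall)
  }
  list(f1 = 100 * f1, threshold = th, recall = recall, precision = precision)
}

#' Per-time sparsity level of a spatio-temporal solution
#'
#' `s_t = 1 - ||J_.t||_1 / max_tau ||J_.tau||_1`: 0 at the most active time
#' point, 1 at an all-zero column.
#'
#' @param J S x T matrix or [st_source()].
#' @return numeric T-vector in `[0, 1]`.
#' @export
sparsity_level <- function(J) {
  J <- if (inherits(J, "st_source")) J$J else as.matrix(J)
  l1 <- colSums(abs(J))
  if (max(l1) == 0) stop("sparsity level undefined for an all-zero solution")
  1 - l1 / max(l1)
}

#' Per-time L1 activation curve
#'
#' The raw column L1 norms `||J_.t||_1`, an inverse measure of sparsity.
#'
#' @inheritParams sparsity_level
#' @return numeric T-vector.
#' @export
activation_level <- function(J) {
  J <- if (inherits(J, "st_source")) J$J else as.matrix(J)
  colSums(abs(J))
}

#' Typical-trial selection and pairwise rank-test win counts
#'
#' `reports` is a long data frame with columns `method`, `trial`, `cell`
#' (an identifier for a time-point-by-configuration cell) and the four
#' measures `emd`, `dle` (lower better), `auc`, `f1` (higher better).
#'
#' The typical trial of each method is the trial sitting at the median
#' position after ordering trials by their summed ranks over all four
#' measures (trial measures are averaged over cells first). The win-count
#' table gives, for each ordered method pair and measure, the percentage of
#' cells in which the first method is significantly better than the second
#' by a two-sided Wilcoxon rank-sum test across trials at `p < alpha`.
#'
#' @param reports long-format data frame as described above.
#' @param alpha significance level for the rank-sum tests (default 0.05).
#' @return list with `typical_trial` (named per method) and `win_counts`
#'   (data frame: method_a, method_b, measure, win_pct).
#' @export
rank_summaries <- function(reports, alpha = 0.05) {
  measures <- c("emd", "dle", "auc", "f1")
  measures <- intersect(measures, names(reports))
  higher_better <- c(emd = FALSE, dle = FALSE, auc = TRUE, f1 = TRUE)
  methods <- unique(reports$method)
  if (length(unique(reports$trial)) < 2 && length(methods) >= 2)
    warning("fewer than 2 trials: rank tests are uninformative")
  typical <- vapply(methods, function(mth) {
    sub <- reports[reports$method == mth, , drop = FALSE]
    agg <- stats::aggregate(sub[measures], by = list(trial = sub$trial),
                            FUN = base::mean)
    rk <- rowSums(vapply(measures, function(ms) {
      v <- agg[[ms]]
      rank(if (higher_better[[ms]]) -v else v)
    }, numeric(nrow(agg))))
    agg$trial[order(rk)][ceiling(nrow(agg) / 2)]
  }, reports$trial[1])
  if (length(methods) == 0) stop("no methods in reports")
  win <- NULL
  if (length(methods) >= 2) {
    cells <- unique(reports$cell %||% "all")
    if (is.null(reports$cell)) reports$cell <- "all"
    combos <- expand.grid(a = methods, b = methods,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$a != combos$b, , drop = FALSE]
    rows <- list()
    for (r in seq_len(nrow(combos))) {
      for (ms in measures) {
        wins <- 0L
        for (cl in cells) {
          xa <- reports[reports$method == combos$a[r] &
                          reports$cell == cl, ms]
          xb <- reports[reports$method == combos$b[r] &
                          reports$cell == cl, ms]
          if (length(xa) < 2 || length(xb) < 2) next
          p <- suppressWarnings(
            stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
          better <- if (higher_better[[ms]]) stats::median(xa) >
            stats::median(xb) else stats::median(xa) < stats::median(xb)
          if (is.finite(p) && p < alpha && better) wins <- wins + 1L
        }
        rows[[length(rows) + 1L]] <-
          data.frame(method_a = combos$a[r], method_b = combos$b[r],
                     measure = ms, win_pct = 100 * wins / length(cells))
      }
    }
    win <- do.call(rbind, rows)
  }
  # with a single method only the typical-trial part is available; the
  # pairwise table needs >= 2 methods and is returned as NULL
  list(typical_trial = typical, win_counts = win)
}

#' Full quality report for one estimate against the simulated truth
#'
#' @param truth,estimate [st_source()] or S x T matrices.
#' @param space the [source_space()] used for distances.
#' @param patch_centers true patch-center indices (for DLE).
#' @param time_points integer vector of columns to evaluate (default: all).
#' @param metrics subset of `c("emd", "dle", "auc", "f1")`.
#' @return data frame with one row per evaluated time point.
#' @export
quality_report <- function(truth, estimate, space, patch_centers,
                           time_points = NULL,
                           metrics = c("emd", "dle", "auc", "f1")) {
  Jt <- if (inherits(truth, "st_source")) truth$J else as.matrix(truth)
  Je <- if (inherits(estimate, "st_source")) estimate$J else
    as.matrix(estimate)
  tp <- time_points %||% seq_len(ncol(Jt))
  rows <- lapply(tp, function(t) {
    out <- list(time = t)
    active <- any(Jt[, t] != 0) && any(Jt[, t] == 0)
    if ("emd" %in% metrics)
      out$emd <- if (any(Jt[, t] != 0) && any(Je[, t] != 0))
        emd(Jt[, t], Je[, t], space$positions) else NA_real_
    if ("dle" %in% metrics)
      out$dle <- if (max(abs(Je[, t])) > 0)
        dle(Jt[, t], Je[, t], space$positions, space$adjacency,
            patch_centers) else NA_real_
    if ("auc" %in% metrics)
      out$auc <- if (active) roc_auc(Jt[, t], Je[, t]) else NA_real_
    if ("f1" %in% metrics)
      out$f1 <- if (active) f1_optimal(Jt[, t], Je[, t])$f1 else NA_real_
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
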