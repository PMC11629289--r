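# Evaluation metrics (confusion-matrix summaries, ROC/AUC) and the
# Mann-Whitney U group comparison, defined once and shared by all stages.

#' Confusion-matrix classification metrics
#'
#' Sensitivity (recall), specificity, accuracy, precision, and the F1 score
#' (harmonic mean of precision and sensitivity). Metrics with a zero
#' denominator are returned as `NA` (a flagged undefined value), never
#' silently as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts, or `tp` may be a list with
#'   those named elements.
#' @return A list with `Se`, `Sp`, `Acc`, `Precision`, `F1`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    cc <- tp; tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop_with("confusion counts must be non-negative")
  if (sum(counts) == 0) stop_with("all confusion counts are zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / sum(counts)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(se) || (prec + se) == 0) {
    NA_real_
  } else {
    2 * prec * se / (prec + se)
  }
  list(Se = se, Sp = sp, Acc = acc, Precision = prec, F1 = f1)
}

#' ROC curve and area under the curve
#'
#' Sweeps every threshold induced by the unique scores (prediction positive
#' when `score >= threshold`), records the true/false positive rates, and
#' integrates by the trapezoidal rule. With tied scores grouped, the result
#' equals the pairwise-win probability
#' `P(score_pos > score_neg) + 0.5 * P(tie)` (the Mann-Whitney U
#' interpretation of the AUC).
#'
#' @param labels Vector of class labels; both classes must be present.
#' @param scores Numeric scores, higher meaning more positive.
#' @param positive The positive-class label.
#' @return A list with `auc` and `roc`, a data.frame of
#'   `threshold`, `fpr`, `tpr` (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(labels, scores, positive) {
  if (length(labels) != length(scores)) stop_with("labels/scores length mismatch")
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_with("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(k) sum(is_pos & scores >= k) / n_pos, numeric(1))
  fpr <- vapply(thr, function(k) sum(!is_pos & scores >= k) / n_neg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Mann-Whitney U test with significance stars
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is used when `n_a + n_b <= 20` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Stars follow the conventional thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise.
#'
#' @param a,b Numeric samples, at least 3 values each.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An object of class `group_test` with `U`, `p_value`, `stars`,
#'   `exact`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 3L || length(b) < 3L) {
    stop_with("each sample needs at least 3 values")
  }
  no_ties <- !anyDuplicated(c(a, b))
  use_exact <- (length(a) + length(b) <= 20L) && no_ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative, exact = use_exact, correct = TRUE))
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(U = unname(wt$statistic), p_value = p, stars = stars,
                 exact = use_exact, alternative = alternative),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> U = %g, p = %.4g (%s, %s)\n", x$U, x$p_value,
              x$stars, if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Group statistics table (mean +/- SE with significance stars)
#'
#' For every feature and every requested pair of class labels, reports the
#' per-group mean and standard error and the Mann-Whitney U comparison.
#'
#' @param table Feature table with a `label` column.
#' @param pairs List of length-2 character vectors of labels to compare.
#' @param features Features to summarize (default: all numeric features).
#' @return A data.frame with one row per feature x pair.
#' @export
group_stats <- function(table, pairs, features = NULL) {
  features <- features %||% feature_cols(table)
  out <- list()
  for (pr in pairs) {
    xa <- table[table$label == pr[1], , drop = FALSE]
    xb <- table[table$label == pr[2], , drop = FALSE]
    if (!nrow(xa) || !nrow(xb)) {
      stop_with("pair %s:%s has an empty group", pr[1], pr[2])
    }
    for (f in features) {
      mw <- mann_whitney_u(xa[[f]], xb[[f]])
      out[[length(out) + 1L]] <- data.frame(
        feature = f, group_a = pr[1], group_b = pr[2],
        mean_a = mean(xa[[f]]), se_a = stats::sd(xa[[f]]) / sqrt(nrow(xa)),
        mean_b = mean(xb[[f]]), se_b = stats::sd(xb[[f]]) / sqrt(nrow(xb)),
        U = mw$U, p_value = mw$p_value, stars = mw$stars,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
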