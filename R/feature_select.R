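# Data-preparation stage: variance filter, pairwise-correlation filter with
# an alpha2-priority rule, train-statistics standardization, and a PCA
# explained-variance audit.

#' Variance filter
#'
#' Drops features whose sample variance (denominator `n - 1`, computed on
#' raw, unstandardized values) is strictly below `threshold`.
#'
#' @param table Feature table (data.frame; metadata columns `spectrum_id`,
#'   `patient_id`, `point_id`, `label` are passed through untouched).
#' @param threshold Variance threshold; default 1.
#' @return A list with `table` (filtered), `dropped` (character), and
#'   `variance` (named numeric vector over the input features).
#' @export
variance_filter <- function(table, threshold = 1) {
  if (nrow(table) < 2L) stop_with("variance filter needs at least 2 rows")
  feats <- feature_cols(table)
  v <- vapply(table[feats], stats::var, numeric(1))
  dropped <- feats[v < threshold]
  list(table = table[, setdiff(names(table), dropped), drop = FALSE],
       dropped = dropped, variance = v)
}

#' Pairwise-correlation filter
#'
#' For every feature pair with `|Pearson r| > threshold` exactly one member
#' is dropped, iterating (largest `|r|` first) until no violating pair
#' remains. The member kept is the one appearing earlier in `priority`;
#' when neither is listed, the feature with the higher raw variance survives,
#' ties broken by input column order. The default priority keeps the
#' long-component contribution `alpha2` over its complement `alpha1`.
#'
#' @param table Feature table with at least 3 rows.
#' @param threshold Absolute-correlation threshold; default 0.7.
#' @param priority Character vector of preferred features, most preferred
#'   first.
#' @return A list with `table`, `dropped` (data.frame of `feature`,
#'   `kept_partner`, `abs_r`), and `correlation` (matrix over the input
#'   features).
#' @export
correlation_filter <- function(table, threshold = 0.7,
                               priority = c("alpha2", "alpha1")) {
  if (nrow(table) < 3L) stop_with("correlation filter needs at least 3 rows")
  feats <- feature_cols(table)
  dropped <- data.frame(feature = character(), kept_partner = character(),
                        abs_r = numeric(), stringsAsFactors = FALSE)
  cor_full <- if (length(feats) >= 2L) {
    stats::cor(table[feats])
  } else {
    matrix(1, length(feats), length(feats), dimnames = list(feats, feats))
  }
  if (length(feats) < 2L) {
    return(list(table = table, dropped = dropped, correlation = cor_full))
  }
  variance <- vapply(table[feats], stats::var, numeric(1))
  keep <- feats
  repeat {
    cm <- abs(stats::cor(table[keep]))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) <= threshold) break
    ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- keep[sort(ij)]
    rank_of <- function(f) {
      p <- match(f, priority)
      if (!is.na(p)) p else length(priority) + 1
    }
    pr <- vapply(pair, rank_of, numeric(1))
    kept <- if (pr[1] != pr[2]) {
      pair[which.min(pr)]
    } else if (variance[pair[1]] != variance[pair[2]]) {
      pair[which.max(variance[pair])]
    } else {
      pair[1] # tie: input column order
    }
    drop <- setdiff(pair, kept)
    dropped <- rbind(dropped, data.frame(
      feature = drop, kept_partner = kept,
      abs_r = cm[pair[1], pair[2]], stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  list(table = table[, c(setdiff(names(table), feats), keep), drop = FALSE],
       dropped = dropped, correlation = cor_full)
}

#' Standardize features with train-set statistics
#'
#' Rescales each feature to zero mean and unit variance. When `stats` is
#' supplied (from a previous call on training data) its center/scale are
#' applied unchanged, so test rows never contribute to the scaling -- the
#' standard guard against train/test leakage.
#'
#' @param table Feature table.
#' @param stats Optional list with `center` and `scale` named vectors.
#' @return A list with `table` (standardized), `center`, `scale`.
#' @export
standardize_features <- function(table, stats = NULL) {
  feats <- feature_cols(table)
  if (is.null(stats)) {
    center <- vapply(table[feats], mean, numeric(1))
    scale <- vapply(table[feats], stats::sd, numeric(1))
    if (any(scale == 0)) {
      stop_with("constant feature(s): %s (should have been variance-filtered)",
                paste(feats[scale == 0], collapse = ", "))
    }
  } else {
    center <- stats$center[feats]
    scale <- stats$scale[feats]
  }
  for (f in feats) table[[f]] <- (table[[f]] - center[[f]]) / scale[[f]]
  list(table = table, center = center, scale = scale)
}

#' PCA explained-variance audit
#'
#' Eigen-decomposition of the sample covariance of an already-standardized
#' feature table (i.e. its correlation structure). Reported fractions are
#' sorted in decreasing order and sum to 1. This is an audit only: the
#' classifiers consume the original retained features, not the principal
#' components.
#'
#' @param table Standardized feature table with more rows than features.
#' @return A list with `fractions` (per-component explained-variance
#'   fractions), `sdev`, and `rank_deficient` flag.
#' @export
pca_variance_audit <- function(table) {
  feats <- feature_cols(table)
  if (nrow(table) < length(feats) + 1L) {
    stop_with("PCA audit needs at least features + 1 rows")
  }
  pc <- stats::prcomp(table[feats], center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  fr <- sort(ev / sum(ev), decreasing = TRUE)
  list(fractions = fr, sdev = pc$sdev,
       rank_deficient = any(ev < 1e-12 * max(ev)))
}

#' Full data-preparation pipeline
#'
#' Applies, in order: the raw-variance filter (`< threshold` dropped), the
#' pairwise-correlation filter with the `alpha2`-over-`alpha1` priority,
#' standardization, and the PCA explained-variance audit. Classifiers are
#' meant to consume `table` (retained features, unstandardized -- model
#' training re-standardizes on each training split).
#'
#' @param table Feature table with columns `I_f`, `alpha1`, `alpha2`,
#'   `tau1`, `tau2` (or any numeric features).
#' @param var_threshold Variance threshold (default 1).
#' @param cor_threshold Absolute-correlation threshold (default 0.7).
#' @param priority Preferred-feature order for correlated pairs.
#' @return A list with `table` (retained raw features + metadata) and
#'   `report`, an object of class `selection_report` holding
#'   `variance_per_feature`, `dropped_by_variance`, `correlation_matrix`,
#'   `dropped_by_correlation`, `retained_features`,
#'   `pca_explained_fraction`.
#' @export
select_features <- function(table, var_threshold = 1, cor_threshold = 0.7,
                            priority = c("alpha2", "alpha1")) {
  vf <- variance_filter(table, threshold = var_threshold)
  cf <- correlation_filter(vf$table, threshold = cor_threshold,
                           priority = priority)
  retained <- feature_cols(cf$table)
  std <- standardize_features(cf$table)
  pca <- pca_variance_audit(std$table)
  report <- structure(list(
    variance_per_feature = vf$variance,
    dropped_by_variance = vf$dropped,
    correlation_matrix = cf$correlation,
    dropped_by_correlation = cf$dropped,
    retained_features = retained,
    pca_explained_fraction = pca$fractions,
    pca_rank_deficient = pca$rank_deficient), class = "selection_report")
  list(table = cf$table, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  retained:", paste(x$retained_features, collapse = ", "), "\n")
  if (length(x$dropped_by_variance)) {
    cat("  dropped by variance:",
        paste(x$dropped_by_variance, collapse = ", "), "\n")
  }
  if (nrow(x$dropped_by_correlation)) {
    cat(sprintf("  dropped by correlation: %s (kept %s, |r|=%.2f)\n",
                x$dropped_by_correlation$feature,
                x$dropped_by_correlation$kept_partner,
                x$dropped_by_correlation$abs_r), sep = "")
  }
  cat("  PCA explained fractions:",
      paste(sprintf("%.1f%%", 100 * x$pca_explained_fraction),
            collapse = ", "), "\n")
  invisible(x)
}
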