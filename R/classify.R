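# Repeated-split training and evaluation of the four classifiers:
# LDA baseline, random forest, polynomial-kernel SVC, logistic regression.

#' Repeated train/test split protocol
#'
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param n_repeats Number of independent reshuffles (default 10).
#' @param stratified Preserve class proportions in each split.
#' @param seed Integer seed; each repeat derives its own stream.
#' @return An object of class `split_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.8, n_repeats = 10,
                           stratified = TRUE, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_with("train_fraction must lie in (0, 1)")
  }
  if (n_repeats < 1) stop_with("n_repeats must be at least 1")
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_protocol")
}

#' Comparison specification
#'
#' @param mode `"binary"` or `"multiclass"`.
#' @param positive Positive-class label (binary mode; the tumor class).
#' @param classes Class labels entering the comparison. Defaults to
#'   `c(positive, "liver")` in binary mode.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(mode = c("binary", "multiclass"), positive = NULL,
                            classes = NULL) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    if (is.null(positive)) stop_with("binary comparison needs a positive class")
    classes <- classes %||% c(positive, "liver")
    if (length(classes) != 2L) stop_with("binary comparison needs 2 classes")
  } else {
    classes <- classes %||% c("BT", "HCC", "MTS")
    if (length(classes) < 3L) stop_with("multiclass comparison needs >= 3 classes")
  }
  structure(list(mode = mode, positive = positive, classes = classes),
            class = "comparison_spec")
}

#' Stratified train/test split for one repeat
#'
#' Shuffles rows with a stream derived from `(seed, repeat_index)` and takes
#' `train_fraction` of each class for training (spectrum-level split; no
#' patient grouping). Train and test partition the table.
#'
#' @param table Feature table with a `label` column; every class needs at
#'   least 2 rows (5 recommended).
#' @param protocol A [split_protocol()].
#' @param repeat_index Repeat number (1-based).
#' @return A list with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, protocol, repeat_index = 1) {
  tab <- table(table$label)
  if (any(tab < 2L)) {
    stop_with("every class needs at least 2 rows (got: %s)",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  idx_train <- integer(0)
  with_local_seed(derive_seed(protocol$seed, repeat_index), {
    if (protocol$stratified) {
      for (lab in names(tab)) {
        rows <- which(table$label == lab)
        n_tr <- round(length(rows) * protocol$train_fraction)
        n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
        idx_train <- c(idx_train, sample(rows, n_tr))
      }
    } else {
      n_tr <- round(nrow(table) * protocol$train_fraction)
      idx_train <- sample(seq_len(nrow(table)), n_tr)
    }
  })
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE])
}

#' Train one classifier
#'
#' Fits one of the four models on a training table. LDA, SVC and LR consume
#' features standardized with statistics computed on these training rows
#' only (stored in the model and re-applied at prediction time); the random
#' forest consumes raw features. The forest uses 100 trees, bootstrap
#' resampling with replacement and `floor(sqrt(d))` candidate features per
#' split; the SVC a polynomial kernel (degree 3, cost 1 by default); LR an
#' unpenalized maximum-likelihood fit (binary: binomial GLM; multiclass:
#' multinomial).
#'
#' @param kind One of `"lda"`, `"rf"`, `"svc"`, `"lr"`.
#' @param train Training feature table with a `label` column.
#' @param features Feature columns to use (default: all numeric features).
#' @param config Optional list: `ntree`, `degree`, `cost`, `rng_seed` (for
#'   the forest's bootstrap).
#' @return An object of class `trf_model` exposing [predict.trf_model()].
#' @export
train_model <- function(kind = c("lda", "rf", "svc", "lr"), train,
                        features = NULL, config = list()) {
  kind <- match.arg(kind)
  features <- features %||% feature_cols(train)
  y <- factor(train$label)
  if (nlevels(y) < 2L) stop_with("training data contain a single class")
  scaler <- NULL
  x <- train[, features, drop = FALSE]
  if (kind != "rf") {
    std <- standardize_features(train[, c("label", features)])
    scaler <- list(center = std$center, scale = std$scale)
    x <- std$table[, features, drop = FALSE]
  }
  dat <- cbind(x, .y = y)
  fit <- switch(kind,
    lda = MASS::lda(x, grouping = y),
    rf = with_local_seed(config$rng_seed %||% NULL,
      randomForest::randomForest(
        x = x, y = y, ntree = config$ntree %||% 100,
        mtry = max(1L, floor(sqrt(length(features)))), replace = TRUE)),
    svc = e1071::svm(x = x, y = y, kernel = "polynomial",
                     degree = config$degree %||% 3, cost = config$cost %||% 1,
                     probability = TRUE, scale = FALSE),
    lr = if (nlevels(y) == 2L) {
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    } else {
      nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 500)
    })
  structure(list(kind = kind, fit = fit, scaler = scaler,
                 features = features, classes = levels(y)),
            class = "trf_model")
}

#' Predict classes and per-class scores
#'
#' Returns the predicted class per row and a continuous score per class:
#' vote fractions for the random forest, decision-function values (binary)
#' or Platt probabilities (multiclass) for the SVC, fitted probabilities for
#' LR, and posterior probabilities for LDA.
#'
#' @param object A `trf_model`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return A list with `class` (factor) and `scores` (matrix, one column per
#'   class).
#' @export
predict.trf_model <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$scaler)) {
    for (f in object$features) {
      x[[f]] <- (x[[f]] - object$scaler$center[[f]]) / object$scaler$scale[[f]]
    }
  }
  cls <- object$classes
  scores <- switch(object$kind,
    lda = stats::predict(object$fit, x)$posterior,
    rf = stats::predict(object$fit, x, type = "vote", norm.votes = TRUE),
    svc = {
      pr <- stats::predict(object$fit, x, probability = TRUE,
                           decision.values = TRUE)
      if (length(cls) == 2L) {
        dv <- attr(pr, "decision.values")
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        s <- matrix(c(dv[, 1], -dv[, 1]), ncol = 2)
        colnames(s) <- c(first, setdiff(cls, first))
        s[, cls, drop = FALSE]
      } else {
        attr(pr, "probabilities")[, cls, drop = FALSE]
      }
    },
    lr = if (length(cls) == 2L) {
      p2 <- stats::predict(object$fit, newdata = x, type = "response")
      s <- cbind(1 - p2, p2)
      colnames(s) <- cls
      s
    } else {
      stats::predict(object$fit, newdata = x, type = "probs")[, cls,
                                                              drop = FALSE]
    })
  scores <- as.matrix(scores)[, cls, drop = FALSE]
  pred <- factor(cls[max.col(scores, ties.method = "first")], levels = cls)
  list(class = pred, scores = scores)
}

# One-vs-rest confusion counts for a class.
ovr_counts <- function(actual, predicted, positive) {
  list(tp = sum(actual == positive & predicted == positive),
       fp = sum(actual != positive & predicted == positive),
       tn = sum(actual != positive & predicted != positive),
       fn = sum(actual == positive & predicted != positive))
}

#' Evaluate one classifier under the repeated-split protocol
#'
#' For each repeat: stratified 80/20 split, feature scaling fitted on the
#' training rows only, model fit, scoring of the held-out rows, and
#' computation of sensitivity, specificity, accuracy, F1 and ROC-AUC
#' (binary: tumor class positive; multiclass: one-vs-rest per class).
#' Metrics are aggregated as mean and standard deviation over repeats;
#' training-set accuracy is recorded per repeat. A repeat whose test set
#' degenerates to a single class is redrawn with the next derived seed.
#'
#' @param table Post-selection feature table.
#' @param comparison A [comparison_spec()].
#' @param kind Classifier kind (see [train_model()]).
#' @param protocol A [split_protocol()].
#' @param features Feature columns (default: all numeric features; the LDA
#'   baseline of the study restricts to `c("alpha2", "tau2")`).
#' @param config Model configuration passed to [train_model()].
#' @return An object of class `evaluation_report` with `raw` (per-repeat,
#'   per-class metrics), `summary` (mean/sd per class and metric), `roc`
#'   (ROC points per repeat and class), `train_accuracy`, `imbalance_ratio`.
#' @export
evaluate_comparison <- function(table, comparison, kind = "rf",
                                protocol = split_protocol(), features = NULL,
                                config = list()) {
  stopifnot(inherits(comparison, "comparison_spec"))
  dat <- table[table$label %in% comparison$classes, , drop = FALSE]
  missing_cls <- setdiff(comparison$classes, unique(dat$label))
  if (length(missing_cls)) {
    stop_with("classes absent from table: %s",
              paste(missing_cls, collapse = ", "))
  }
  features <- features %||% feature_cols(dat)
  eval_classes <- if (comparison$mode == "binary") {
    comparison$positive
  } else {
    comparison$classes
  }
  raw <- list(); rocs <- list(); redraws <- 0L
  for (r in seq_len(protocol$n_repeats)) {
    attempt <- 0L
    repeat {
      sp <- split_train_test(dat, protocol,
                             repeat_index = r + attempt * 100003L)
      if (length(unique(sp$test$label)) >= 2L) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 50L) stop_with("could not draw a two-class test set")
    }
    cfg <- config
    cfg$rng_seed <- derive_seed(protocol$seed, 900000L + r)
    model <- train_model(kind, sp$train, features = features, config = cfg)
    pred_te <- stats::predict(model, sp$test)
    pred_tr <- stats::predict(model, sp$train)
    train_acc <- mean(as.character(pred_tr$class) == sp$train$label)
    for (cl in eval_classes) {
      cm <- confusion_metrics(ovr_counts(sp$test$label,
                                         as.character(pred_te$class), cl))
      ra <- roc_auc(sp$test$label, pred_te$scores[, cl], positive = cl)
      raw[[length(raw) + 1L]] <- data.frame(
        repeat_index = r, class = cl, Se = cm$Se, Sp = cm$Sp, Acc = cm$Acc,
        F1 = cm$F1, AUC = ra$auc, train_acc = train_acc,
        stringsAsFactors = FALSE)
      rocs[[sprintf("%s_rep%02d", cl, r)]] <- ra$roc
    }
  }
  raw <- do.call(rbind, raw)
  metrics <- c("Se", "Sp", "Acc", "F1", "AUC")
  summ <- do.call(rbind, lapply(split(raw, raw$class), function(d) {
    data.frame(class = d$class[1], metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(d[[m]]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  summ$sd[is.na(summ$sd)] <- 0 # single repeat
  rownames(summ) <- NULL
  cls_n <- table(dat$label)
  structure(list(
    comparison = comparison, model = kind, raw = raw, summary = summ,
    roc = rocs, train_accuracy = raw$train_acc[!duplicated(raw$repeat_index)],
    imbalance_ratio = max(cls_n) / min(cls_n), redraws = redraws,
    protocol = protocol, features = features), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, model=%s, %d repeats\n",
              paste(x$comparison$classes, collapse = "/"), x$model,
              x$protocol$n_repeats))
  for (cl in unique(x$summary$class)) {
    d <- x$summary[x$summary$class == cl, ]
    cat(sprintf("  %s: %s\n", cl,
                paste(sprintf("%s %.2f +/- %.2f", d$metric, d$mean, d$sd),
                      collapse = ", ")))
  }
  cat(sprintf("  mean train accuracy %.3f; imbalance ratio %.2f\n",
              mean(x$train_accuracy), x$imbalance_ratio))
  invisible(x)
}
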