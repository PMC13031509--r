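#' Confusion counts
#'
#' Tallies true/false positives and negatives with 1 = positive case (e.g.
#' confirmed CAD).
#'
#' @param labels Numeric 0/1 truth vector.
#' @param predictions Numeric 0/1 predicted classes.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.numeric(labels)
  predictions <- as.numeric(predictions)
  if (length(labels) != length(predictions)) {
    abort("`labels` and `predictions` must have equal length.",
          class = "shapsel_config_error")
  }
  structure(
    list(
      tp = sum(labels == 1 & predictions == 1),
      fp = sum(labels == 0 & predictions == 1),
      tn = sum(labels == 0 & predictions == 0),
      fn = sum(labels == 1 & predictions == 0)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, degenerate = TRUE)
  else list(value = num / den, degenerate = FALSE)
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and the F1 score
#' `2*precision*recall/(precision+recall)`.  Any 0/0 ratio is reported as 0
#' and flagged in the `"degenerate"` attribute rather than thrown.
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row tibble with columns `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`; attribute `"degenerate"` names any
#'   flagged metrics.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  acc <- safe_ratio(counts$tp + counts$tn, total)
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp)
  sens <- safe_ratio(counts$tp, counts$tp + counts$fn)
  spec <- safe_ratio(counts$tn, counts$tn + counts$fp)
  f1 <- if (prec$value + sens$value == 0) {
    list(value = 0, degenerate = TRUE)
  } else {
    list(value = 2 * prec$value * sens$value / (prec$value + sens$value),
         degenerate = FALSE)
  }
  out <- tibble(
    accuracy = acc$value, precision = prec$value, sensitivity = sens$value,
    specificity = spec$value, f1 = f1$value
  )
  flags <- c(accuracy = acc$degenerate, precision = prec$degenerate,
             sensitivity = sens$degenerate, specificity = spec$degenerate,
             f1 = f1$degenerate)
  attr(out, "degenerate") <- names(flags)[flags]
  out
}

#' Area under the ROC curve
#'
#' The probability that a random positive case scores above a random
#' negative case, ties counted one half — the normalised Mann-Whitney
#' statistic, computed through midranks.
#'
#' @param labels Numeric 0/1 truth vector (both classes required).
#' @param scores Numeric scores (e.g. predicted probabilities).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.",
          class = "shapsel_config_error")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined with only one class present.",
          class = "shapsel_data_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs at every distinct score threshold,
#' exportable for external plotting.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.numeric(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(labels == 1 & scores >= t) / n1,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(labels == 0 & scores >= t) / n0,
                 numeric(1))
  )
}

# ---- leakage-safe fold pipeline ------------------------------------------

# Assemble the training and test data of one fold: restrict to `subset`,
# fit min-max bounds on the training part only, normalise both, then SMOTE
# the training part (only) to balance.  Synthetic rows are tagged so tests
# can assert they never reach a test fold.
assemble_fold <- function(data, plan, fold_i, subset, smote = smote_config(),
                          label = "label") {
  ft <- as_feature_table(data, label)
  feats <- ft_feature_names(ft)
  missing <- setdiff(subset, feats)
  if (length(missing) > 0L) {
    abort(paste0("Subset feature(s) not in data: ",
                 paste(missing, collapse = ", ")),
          class = "shapsel_config_error")
  }
  tbl <- as_tibble(ft)[c(subset, ft_label_col(ft))]
  ft_sub <- feature_table(tbl, label = ft_label_col(ft))
  train_rows <- plan$row[plan$fold != fold_i]
  test_rows <- plan$row[plan$fold == fold_i]
  train <- rebuild_ft(as_tibble(ft_sub)[train_rows, ], ft_sub)
  test <- rebuild_ft(as_tibble(ft_sub)[test_rows, ], ft_sub)
  rec <- minmax_fit(train)
  train_n <- minmax_normalize(rec, train)
  test_n <- minmax_normalize(rec, test)
  fold_smote <- smote_config(smote$k_neighbors,
                             derive_seed(smote$seed, fold_i))
  train_b <- smote_oversample(train_n, fold_smote)
  list(train = train_b, test = test_n, test_rows = test_rows,
       synthetic = attr(train_b, "synthetic"))
}

fold_scores <- function(data, plan, fold_i, subset, clf, smote, label) {
  fd <- assemble_fold(data, plan, fold_i, subset, smote, label)
  model <- tryCatch(
    fit_classifier(clf, ft_matrix(fd$train), ft_labels(fd$train)),
    error = function(e) {
      abort(paste0("Training failed in fold ", fold_i, ": ",
                   conditionMessage(e)),
            class = "shapsel_eval_error")
    }
  )
  prob <- predict_prob(model, ft_matrix(fd$test))
  list(labels = ft_labels(fd$test), prob = prob,
       pred = as.numeric(prob >= 0.5))
}

#' Cross-validated accuracy of a feature subset
#'
#' Mean stratified-CV accuracy of `clf` on the given feature subset, with
#' the leakage-safe per-fold pipeline: restrict columns, fit min-max bounds
#' on the training folds, normalise both parts, SMOTE-balance the training
#' part only, fit, and score the held-out fold.  Deterministic given the
#' fold-plan, SMOTE and classifier seeds.
#'
#' @param data A [feature_table()] or data frame (encoded numeric
#'   features).
#' @param subset Character vector of feature names (non-empty).
#' @param clf A [classifier_spec()].
#' @param folds A [stratified_kfold_split()] plan.
#' @param smote A [smote_config()].
#' @param label Label column name.
#' @return Mean accuracy across folds (a single number).
#' @export
evaluate_subset <- function(data, subset, clf, folds,
                            smote = smote_config(), label = "label") {
  if (length(subset) == 0L) {
    abort("`subset` must contain at least one feature.",
          class = "shapsel_config_error")
  }
  k <- attr(folds, "k")
  accs <- vapply(seq_len(k), function(i) {
    sc <- fold_scores(data, folds, i, subset, clf, smote, label)
    mean(sc$pred == sc$labels)
  }, numeric(1))
  mean(accs)
}

#' Full cross-validated performance report
#'
#' Runs the same leakage-safe fold pipeline as [evaluate_subset()] but
#' records all diagnostic metrics (accuracy, precision, sensitivity,
#' specificity, F1, AUC) per fold, plus their mean and sample (n-1)
#' standard deviation.
#'
#' @inheritParams evaluate_subset
#' @return An `eval_report` with fields `per_fold` (tibble, one row per
#'   fold), `summary` (tibble: metric, mean, sd), `subset`, `clf`, and the
#'   seeds used.  `tidy()` returns the per-fold tibble, `glance()` the
#'   one-row summary.
#' @export
cross_validated_report <- function(data, subset, clf, folds,
                                   smote = smote_config(), label = "label") {
  if (length(subset) == 0L) {
    abort("`subset` must contain at least one feature.",
          class = "shapsel_config_error")
  }
  k <- attr(folds, "k")
  per_fold <- map(seq_len(k), function(i) {
    sc <- fold_scores(data, folds, i, subset, clf, smote, label)
    m <- metrics_from_counts(confusion_counts(sc$labels, sc$pred))
    auc <- if (length(unique(sc$labels)) == 2L) {
      roc_auc(sc$labels, sc$prob)
    } else {
      NA_real_
    }
    bind_cols(tibble(fold = i), m, tibble(auc = auc))
  })
  per_fold <- bind_rows(per_fold)
  metric_cols <- c("accuracy", "precision", "sensitivity", "specificity",
                   "f1", "auc")
  summ <- tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols,
                         function(m) mean(per_fold[[m]], na.rm = TRUE),
                         numeric(1))),
    sd = unname(vapply(metric_cols,
                       function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                       numeric(1)))
  )
  structure(
    list(per_fold = per_fold, summary = summ, subset = subset,
         clf = clf,
         seeds = list(folds = attr(folds, "seed"), smote = smote$seed,
                      model = clf$seed)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$clf$kind, " on ", length(x$subset),
      " feature(s), k = ", nrow(x$per_fold), " folds\n", sep = "")
  print(report_percent_table(x))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  x$per_fold
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  out <- as_tibble(wide)
  out$n_features <- length(x$subset)
  out$classifier <- x$clf$kind
  out
}

#' Report as "mean ± sd" percentage strings
#'
#' Formats an [cross_validated_report()] the way diagnostic-performance
#' tables are conventionally printed: percentages with two decimals.
#'
#' @param report An `eval_report`.
#' @return Tibble with `metric` and `value` (e.g. `"93.30 ± 5.89"`).
#' @export
report_percent_table <- function(report) {
  s <- report$summary
  tibble(
    metric = s$metric,
    value = sprintf("%.2f ± %.2f", 100 * s$mean, 100 * s$sd)
  )
}

#' Write an evaluation report
#'
#' @param report An `eval_report`.
#' @param path CSV path for the formatted table; a JSON sidecar with the
#'   raw per-fold numbers, subset and seeds goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  readr::write_csv(report_percent_table(report), path)
  js <- jsonlite::toJSON(
    list(per_fold = report$per_fold, summary = report$summary,
         subset = report$subset, classifier = report$clf$kind,
         params = report$clf$params, seeds = report$seeds),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(js, paste0(path, ".json"))
  invisible(path)
}

#' Grid search over hyperparameters
#'
#' Evaluates every combination of the supplied hyperparameter values by
#' mean cross-validated accuracy (same pipeline as [evaluate_subset()])
#' and returns the winning [classifier_spec()].  Ties are broken by grid
#' order (first listed wins).
#'
#' @param data A [feature_table()] or data frame.
#' @param kind Classifier kind.
#' @param grid Named list of hyperparameter value vectors.
#' @param folds A [stratified_kfold_split()] plan.
#' @param smote A [smote_config()].
#' @param subset Feature subset to evaluate on (default: all features).
#' @param seed Model seed stored in the candidate specs.
#' @param label Label column name.
#' @return The winning `classifier_spec`; attribute `"results"` holds a
#'   tibble of every grid point and its score.
#' @export
grid_search <- function(data, kind, grid, folds, smote = smote_config(),
                        subset = NULL, seed = 1, label = "label") {
  if (length(grid) == 0L) {
    abort("`grid` must contain at least one hyperparameter.",
          class = "shapsel_config_error")
  }
  ft <- as_feature_table(data, label)
  subset <- subset %||% ft_feature_names(ft)
  pts <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    params <- as.list(pts[i, , drop = FALSE])
    names(params) <- names(pts)
    spec <- classifier_spec(kind, params, seed = seed)
    scores[i] <- evaluate_subset(ft, subset, spec, folds, smote, label)
  }
  best <- which.max(scores)    # first maximum = grid order tie-break
  results <- as_tibble(pts)
  results$cv_accuracy <- scores
  winner <- classifier_spec(kind, stats::setNames(as.list(pts[best, ]),
                                                  names(pts)), seed = seed)
  attr(winner, "results") <- results
  winner
}
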