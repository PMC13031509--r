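test_that("confusion counts follow the diagnostic definitions", {
  y <- c(rep(1, 216), rep(0, 87))
  # perfect classifier on the imbalanced split
  cc <- confusion_counts(y, y)
  expect_equal(tidy(cc), tibble::tibble(tp = 216, fp = 0, tn = 87, fn = 0))
  # an all-positive predictor
  cc2 <- confusion_counts(y, rep(1, 303))
  expect_equal(tidy(cc2), tibble::tibble(tp = 216, fp = 87, tn = 0, fn = 0))
  # random vectors match a literal four-way counting loop
  set.seed(17)
  lab <- rbinom(50, 1, 0.5); pred <- rbinom(50, 1, 0.5)
  cc3 <- confusion_counts(lab, pred)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:50) {
    if (lab[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (lab[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (lab[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (lab[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  expect_equal(tidy(cc3), tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_error(confusion_counts(c(0, 1), c(1)),
               class = "shapsel_config_error")
})

test_that("metric formulas match hand arithmetic, flagging 0/0 cases", {
  perfect <- metrics_from_counts(confusion_counts(
    c(rep(1, 216), rep(0, 87)), c(rep(1, 216), rep(0, 87))))
  expect_equal(as.numeric(perfect), rep(1, 5))
  expect_length(attr(perfect, "degenerate"), 0)

  # TP=50 FP=50 TN=0 FN=0: acc .5, prec .5, sens 1, spec 0/0 -> flagged 0,
  # F1 = 2 * .5 * 1 / 1.5 = 2/3
  m <- metrics_from_counts(structure(list(tp = 50, fp = 50, tn = 0, fn = 0),
                                     class = "confusion_counts"))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$f1, 2 / 3)
  # 0/50 is a true zero, not a 0/0 degeneracy: nothing is flagged
  expect_length(attr(m, "degenerate"), 0)

  # no positives at all: precision and sensitivity flagged 0, specificity 1
  m2 <- metrics_from_counts(structure(list(tp = 0, fp = 0, tn = 100, fn = 0),
                                      class = "confusion_counts"))
  expect_equal(m2$precision, 0)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_setequal(attr(m2, "degenerate"),
                  c("precision", "sensitivity", "f1"))

  # identities on random integer counts
  set.seed(23)
  for (r in 1:10) {
    cts <- structure(as.list(sample(0:40, 4, replace = TRUE)),
                     names = c("tp", "fp", "tn", "fn"),
                     class = "confusion_counts")
    mm <- metrics_from_counts(cts)
    tot <- cts$tp + cts$fp + cts$tn + cts$fn
    if (tot > 0) expect_equal(mm$accuracy, (cts$tp + cts$tn) / tot)
    expect_equal(mm$sensitivity * (cts$tp + cts$fn), cts$tp)
    if (cts$tp == 0) expect_equal(mm$f1, 0) else expect_gt(mm$f1, 0)
  }
})

test_that("AUC equals the O(n^2) pairwise oracle and handles ties", {
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), class = "shapsel_data_error")

  pairwise_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(29)
  for (r in 1:8) {
    y <- c(0, 1, rbinom(10, 1, 0.5))
    s <- round(runif(12), 1)    # coarse scores force ties
    expect_equal(roc_auc(y, s), pairwise_auc(y, s))
    # invariance under a strictly monotone transform of the scores
    expect_equal(roc_auc(y, qlogis((s + 0.5) / 2)), roc_auc(y, s))
  }
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("the cross-validated report aggregates per-fold metrics faithfully", {
  tbl <- separable_table(n = 40)
  ft <- feature_table(tbl)
  folds <- stratified_kfold_split(ft, k = 5, seed = 6)
  rep1 <- cross_validated_report(ft, "signal",
                                 classifier_spec("decision_tree"), folds)
  # separable data: every fold perfect, zero dispersion
  expect_true(all(abs(tidy(rep1)$accuracy - 1) < 1e-12))
  expect_equal(rep1$summary$sd[rep1$summary$metric == "accuracy"], 0)

  # byte-identical under identical seeds
  rep2 <- cross_validated_report(ft, "signal",
                                 classifier_spec("decision_tree"), folds)
  expect_identical(rep1$per_fold, rep2$per_fold)

  # the report's aggregate accuracy equals both the mean of its per-fold
  # accuracies and the independent evaluate_subset() path
  ft2 <- make_cad_like_fixture("statlog_like")
  folds2 <- stratified_kfold_split(ft2, k = 5, seed = 9)
  clf <- classifier_spec("xgboost", seed = 4)
  rep3 <- cross_validated_report(ft2, ft_feature_names(ft2)[1:4], clf,
                                 folds2)
  agg <- rep3$summary$mean[rep3$summary$metric == "accuracy"]
  expect_equal(agg, mean(rep3$per_fold$accuracy))
  expect_equal(agg, evaluate_subset(ft2, ft_feature_names(ft2)[1:4], clf,
                                    folds2))
  # formatted export carries percentages with two decimals
  pt <- report_percent_table(rep3)
  expect_match(pt$value[1], "^[0-9]+\\.[0-9]{2} ± [0-9]+\\.[0-9]{2}$")
  g <- glance(rep3)
  expect_equal(g$accuracy, agg)
  expect_equal(g$n_features, 4)
})

test_that("grid search picks the exhaustive-evaluation winner with grid-order ties", {
  tbl <- separable_table(n = 30)
  ft <- feature_table(tbl)
  folds <- stratified_kfold_split(ft, k = 5, seed = 11)
  # one-point grid returns that point
  w1 <- grid_search(ft, "decision_tree", list(max_depth = 3), folds)
  expect_equal(w1$params$max_depth, 3)

  # 2 x 2 grid matches independent exhaustive evaluation
  grid <- list(max_depth = c(1, 3), criterion = c("gini", "entropy"))
  w2 <- grid_search(ft, "decision_tree", grid, folds)
  res <- attr(w2, "results")
  expect_equal(nrow(res), 4)
  manual <- vapply(seq_len(nrow(res)), function(i) {
    spec <- classifier_spec("decision_tree",
                            list(max_depth = res$max_depth[i],
                                 criterion = res$criterion[i]))
    evaluate_subset(ft, ft_feature_names(ft), spec, folds)
  }, numeric(1))
  expect_equal(res$cv_accuracy, manual)
  best <- which.max(manual)
  expect_equal(w2$params$max_depth, res$max_depth[best])
  expect_equal(w2$params$criterion, res$criterion[best])
  expect_error(grid_search(ft, "decision_tree", list(), folds),
               class = "shapsel_config_error")
})
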