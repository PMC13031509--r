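make_art <- function(features) {
  id <- lapply(1:3, function(i) setNames(seq_along(features), features))
  ensemble_average_rank(build_frt(id, feature_names = features))
}

test_that("a fully determining binary feature scores perfect CV accuracy", {
  tbl <- separable_table(n = 40)
  ft <- feature_table(tbl)
  folds <- stratified_kfold_split(ft, k = 5, seed = 3)
  acc <- evaluate_subset(ft, "signal", classifier_spec("decision_tree"),
                         folds)
  expect_equal(acc, 1.0)
  # deterministic under identical seeds
  acc2 <- evaluate_subset(ft, "signal", classifier_spec("decision_tree"),
                          folds)
  expect_identical(acc, acc2)
  expect_error(evaluate_subset(ft, character(0),
                               classifier_spec("decision_tree"), folds),
               class = "shapsel_config_error")
})

test_that("pure-noise subsets score at chance level on balanced data", {
  accs <- vapply(1:20, function(s) {
    tbl <- noise_table(n = 60, m = 2, seed = 100 + s)
    ft <- feature_table(tbl)
    folds <- stratified_kfold_split(ft, k = 5, seed = s)
    evaluate_subset(ft, c("noise1", "noise2"),
                    classifier_spec("decision_tree", seed = s), folds)
  }, numeric(1))
  # mean accuracy over 20 seeded draws stays within binomial noise of 0.5
  expect_gt(mean(accs), 0.5 - 3 * sqrt(0.25 / (20 * 60)) - 0.05)
  expect_lt(mean(accs), 0.5 + 3 * sqrt(0.25 / (20 * 60)) + 0.05)
})

test_that("forward selection keeps strict improvers and matches a literal transcription", {
  set.seed(55)
  sp <- synthetic_spec(n = 120, m_informative = 2, m_redundant = 1,
                       m_noise = 3, effect_sizes = c(3, 2.5),
                       imbalance = 0.5, noise_sd = 0.3,
                       fraction_binary = 0, seed = 55)
  ft <- synthesize_dataset(sp)$data
  art <- make_art(ft_feature_names(ft))
  clf <- classifier_spec("decision_tree", seed = 2)
  folds <- stratified_kfold_split(ft, k = 5, seed = 8)
  smote <- smote_config(seed = 4)
  trace <- optimized_forward_selection(ft, art, clf, folds, smote)

  # literal re-transcription of the procedure, written independently:
  # seed with the top-ranked feature, walk the remaining rank order adding
  # a feature iff accuracy strictly improves, then try dropping the seed.
  order_feats <- art$feature
  subset <- order_feats[1]
  best <- evaluate_subset(ft, subset, clf, folds, smote)
  log <- c("seed")
  for (f in order_feats[-1]) {
    s <- evaluate_subset(ft, c(subset, f), clf, folds, smote)
    if (s > best + 1e-12) {
      subset <- c(subset, f); best <- s; log <- c(log, "accept")
    } else {
      log <- c(log, "reject")
    }
  }
  if (length(subset) > 1) {
    s <- evaluate_subset(ft, setdiff(subset, order_feats[1]), clf, folds,
                         smote)
    if (s > best + 1e-12) {
      subset <- setdiff(subset, order_feats[1]); best <- s
      log <- c(log, "removed_top")
    }
  }
  expect_equal(trace$steps$action[seq_along(log)], log)
  expect_equal(trace$final_subset, subset)
  expect_equal(trace$final_score, best)

  # invariants: best-so-far never decreases; final beats the seed alone
  bests <- trace$steps$cv_score_best_before
  bests <- bests[!is.na(bests)]
  expect_true(all(diff(c(trace$steps$cv_score_with[1], bests)) >= 0))
  expect_gte(trace$final_score, trace$steps$cv_score_with[1])
})

test_that("the wrapper performs at most M + 1 subset evaluations", {
  ft <- make_cad_like_fixture("cleveland_like")
  art <- make_art(ft_feature_names(ft))
  folds <- stratified_kfold_split(ft, k = 5, seed = 2)
  trace <- optimized_forward_selection(ft, art,
                                       classifier_spec("decision_tree"),
                                       folds)
  expect_lte(trace$n_evaluations, length(ft_feature_names(ft)) + 1)
})

test_that("a single-feature dataset yields a seed-only trace", {
  tbl <- tibble::tibble(x = c(rnorm(10), rnorm(10, 3)),
                        label = rep(c(0, 1), each = 10))
  ft <- feature_table(tbl)
  art <- make_art("x")
  folds <- stratified_kfold_split(ft, k = 5, seed = 1)
  trace <- optimized_forward_selection(ft, art, classifier_spec("knn"),
                                       folds)
  expect_equal(trace$final_subset, "x")
  expect_equal(nrow(trace$steps), 1)
  expect_equal(trace$steps$action, "seed")
})

test_that("a noise seed is dropped by the top-feature removal check", {
  set.seed(91)
  n <- 80
  f2 <- rnorm(n)                      # fully determines the label
  tbl <- tibble::tibble(
    lure = rnorm(n),                  # pure noise, ranked first
    signal = f2,
    extra = rnorm(n),
    label = as.numeric(f2 > 0)
  )
  ft <- feature_table(tbl)
  art <- make_art(c("lure", "signal", "extra"))
  folds <- stratified_kfold_split(ft, k = 5, seed = 7)
  trace <- optimized_forward_selection(
    ft, art, classifier_spec("knn", list(n_neighbors = 5), seed = 3), folds
  )
  expect_true("removed_top" %in% trace$steps$action)
  expect_false("lure" %in% trace$final_subset)
  expect_true("signal" %in% trace$final_subset)
})

test_that("selection traces serialise to JSON, log and subset files", {
  tbl <- separable_table(n = 20)
  ft <- feature_table(tbl)
  art <- make_art(c("signal", "junk1", "junk2"))
  folds <- stratified_kfold_split(ft, k = 5, seed = 5)
  trace <- optimized_forward_selection(ft, art,
                                       classifier_spec("decision_tree"),
                                       folds)
  base <- file.path(withr::local_tempdir(), "trace")
  write_selection_trace(trace, base)
  js <- jsonlite::fromJSON(paste0(base, ".json"))
  expect_equal(js$final_subset, trace$final_subset)
  expect_equal(js$n_evaluations, trace$n_evaluations)
  expect_equal(readLines(paste0(base, "_subset.txt")), trace$final_subset)
  expect_equal(length(readLines(paste0(base, ".log"))), nrow(trace$steps))
  # tidy/glance views
  expect_equal(nrow(tidy(trace)), nrow(trace$steps))
  expect_equal(glance(trace)$n_selected, length(trace$final_subset))
})
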