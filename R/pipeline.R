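#' Ensemble SHAP feature ranking
#'
#' The ranking phase of the pipeline: prepare the data (drop incomplete
#' cases, label-encode, min-max normalise), train the three heterogeneous
#' ranking classifiers (gradient-boosted trees, random forest, RBF
#' support-vector machine), compute Shapley attributions for each, convert
#' the mean-absolute-attribution importances to ranks, and aggregate them
#' into the feature rank table (FRT) and the sorted ensemble average-rank
#' table (ART).
#'
#' If the class ratio (majority/minority) exceeds `smote_ratio_threshold`
#' the ranking models are trained on a SMOTE-balanced copy; attributions
#' are always computed on (a seeded subsample of) the original cases.
#'
#' @param data A [feature_table()] or data frame (raw; preparation is
#'   applied internally).
#' @param label Label column name.
#' @param classifiers Named list of three [classifier_spec()] objects for
#'   the ranking models; defaults to xgboost/random-forest/SVM with
#'   [default_hyperparameters()].
#' @param n_explain Cap on the number of instances attributions are
#'   computed for (seeded subsample; default 100).  Global importance is a
#'   mean over instances, so a moderate subsample estimates it well.
#' @param max_background Cap on the marginalisation background sample
#'   (default 50).
#' @param n_coalitions Sampled coalitions per instance for the kernel
#'   regression; default `min(2^M - 2, max(2M + 2, 8M))`, i.e. exact
#'   enumeration for small M.
#' @param smote A [smote_config()] for the optional pre-training balance.
#' @param smote_ratio_threshold Majority/minority ratio above which the
#'   ranking models see SMOTE-balanced training data (default 1.5).
#' @param seed Master seed for subsampling and attribution.
#' @return A `shapsel_ranking` list: `frt`, `art`, `importance` (tibble:
#'   method, feature, importance, rank), `attributions` (per-method
#'   [attribution_matrix()]), `prepared` (the prepared table), `config`.
#' @export
rank_features <- function(data, label = "label", classifiers = NULL,
                          n_explain = 100, max_background = 50,
                          n_coalitions = NULL, smote = smote_config(),
                          smote_ratio_threshold = 1.5, seed = 1) {
  classifiers <- classifiers %||% list(
    xgboost = classifier_spec("xgboost", seed = derive_seed(seed, 11L)),
    random_forest = classifier_spec("random_forest",
                                    seed = derive_seed(seed, 12L)),
    svm = classifier_spec("svm", seed = derive_seed(seed, 13L))
  )
  prepared <- prepare_dataset(data, label)
  normalized <- minmax_normalize(prepared)
  normalized <- rebuild_ft(as_tibble(normalized), prepared)
  feats <- ft_feature_names(normalized)
  M <- length(feats)
  n_coalitions <- n_coalitions %||% min(2^M - 2, max(2 * M + 2, 8 * M))
  y <- ft_labels(normalized)
  counts <- table(factor(y, levels = c(0, 1)))
  ratio <- max(counts) / max(1, min(counts))
  smote_applied <- is.finite(ratio) && ratio > smote_ratio_threshold
  train_tbl <- if (smote_applied) {
    smote_oversample(normalized, smote)
  } else {
    normalized
  }
  vf <- value_function_spec(ft_matrix(normalized),
                            max_background = max_background,
                            seed = derive_seed(seed, 21L))
  X_explain <- ft_matrix(normalized)
  if (nrow(X_explain) > n_explain) {
    keep <- with_seed(derive_seed(seed, 22L),
                      sample.int(nrow(X_explain), n_explain))
    X_explain <- X_explain[keep, , drop = FALSE]
  }
  attributions <- list()
  rank_vectors <- list()
  importance_rows <- list()
  for (mi in seq_along(classifiers)) {
    mname <- names(classifiers)[mi]
    spec <- classifiers[[mi]]
    model <- fit_classifier(spec, ft_matrix(train_tbl),
                            ft_labels(train_tbl))
    attr_m <- sampled_shapley(model, X_explain, vf,
                              n_coalitions = n_coalitions,
                              seed = derive_seed(seed, 30L + mi))
    imp <- global_importance(attr_m)
    rv <- rank_from_importance(imp)
    attributions[[mname]] <- attr_m
    rank_vectors[[mname]] <- rv
    importance_rows[[mname]] <- mutate(imp, method = mname,
                                       rank = as.integer(rv))
  }
  frt <- build_frt(rank_vectors, feature_names = feats,
                   method_names = names(classifiers))
  art <- ensemble_average_rank(frt)
  structure(
    list(
      frt = frt, art = art,
      importance = bind_rows(importance_rows)[
        , c("method", "feature", "importance", "rank")],
      attributions = attributions,
      prepared = prepared,
      config = list(label = label, n_explain = n_explain,
                    max_background = max_background,
                    n_coalitions = n_coalitions,
                    smote_applied = smote_applied,
                    smote_ratio_threshold = smote_ratio_threshold,
                    seed = seed,
                    classifiers = map(classifiers,
                                      function(s) c(kind = s$kind, s$params)))
    ),
    class = "shapsel_ranking"
  )
}

#' @export
print.shapsel_ranking <- function(x, ...) {
  cat("<shapsel_ranking> ", nrow(x$art), " features ranked by ",
      length(x$attributions), " methods\n", sep = "")
  print(x$art)
  invisible(x)
}

#' Rank-guided feature selection and final evaluation
#'
#' The selection phase: run [optimized_forward_selection()] guided by the
#' ART, then produce a full [cross_validated_report()] on the final subset.
#'
#' @param data A [feature_table()] or data frame, already prepared (the
#'   `prepared` element of a [rank_features()] result is the usual input).
#' @param art An [ensemble_average_rank()] table for the data's features.
#' @param clf A [classifier_spec()].
#' @param k Number of CV folds (default 10).
#' @param smote A [smote_config()].
#' @param seed Fold-plan seed.
#' @param label Label column name.
#' @return A `shapsel_selection` list: `trace` (selection trace), `report`
#'   (eval report on the final subset), `folds`.
#' @export
select_features <- function(data, art, clf, k = 10,
                            smote = smote_config(), seed = 1,
                            label = "label") {
  ft <- as_feature_table(data, label)
  folds <- stratified_kfold_split(ft, k = k, seed = seed, label = label)
  trace <- optimized_forward_selection(ft, art, clf, folds, smote,
                                       label = label)
  report <- cross_validated_report(ft, trace$final_subset, clf, folds,
                                   smote, label = label)
  structure(list(trace = trace, report = report, folds = folds),
            class = "shapsel_selection")
}

#' @export
print.shapsel_selection <- function(x, ...) {
  print(x$trace)
  print(x$report)
  invisible(x)
}

#' Run the full ranking + selection pipeline
#'
#' Composition of [rank_features()] and [select_features()]: rank all
#' features with the three-classifier Shapley ensemble, then select a
#' subset for each requested classifier and evaluate it with stratified
#' cross-validation.
#'
#' @inheritParams rank_features
#' @param selection_classifiers Named list of [classifier_spec()] objects
#'   to run the wrapper with (default: gradient-boosted trees only).
#' @param k CV folds for selection and evaluation (default 10).
#' @return A `shapsel_run` list: `ranking` and a named list `selections`.
#' @export
run_pipeline <- function(data, label = "label",
                         selection_classifiers = NULL, k = 10,
                         smote = smote_config(), seed = 1, ...) {
  selection_classifiers <- selection_classifiers %||% list(
    xgboost = classifier_spec("xgboost", seed = derive_seed(seed, 41L))
  )
  ranking <- rank_features(data, label = label, smote = smote,
                           seed = seed, ...)
  selections <- imap(selection_classifiers, function(clf, nm) {
    select_features(ranking$prepared, ranking$art, clf, k = k,
                    smote = smote, seed = derive_seed(seed, 42L),
                    label = label)
  })
  structure(list(ranking = ranking, selections = selections,
                 seed = seed),
            class = "shapsel_run")
}

#' @export
print.shapsel_run <- function(x, ...) {
  print(x$ranking)
  for (nm in names(x$selections)) {
    cat("\n-- selection (", nm, ") --\n", sep = "")
    print(x$selections[[nm]])
  }
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes the FRT/ART CSVs, per-method importances, attribution matrices,
#' selection traces and evaluation reports of a pipeline run into a
#' directory, each artifact embedding the run configuration and seeds.
#'
#' @param run A `shapsel_run`, `shapsel_ranking`, or `shapsel_selection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(run, "shapsel_run")) {
    write_artifacts(run$ranking, dir)
    for (nm in names(run$selections)) {
      sel <- run$selections[[nm]]
      write_selection_trace(sel$trace, file.path(dir, paste0("trace_", nm)))
      write_eval_report(sel$report, file.path(dir, paste0("report_", nm,
                                                          ".csv")))
      fold_plan_json(sel$folds, file.path(dir, paste0("folds_", nm,
                                                      ".json")))
    }
    return(invisible(dir))
  }
  if (inherits(run, "shapsel_ranking")) {
    write_rank_table(run$frt, file.path(dir, "frt.csv"))
    write_rank_table(run$art, file.path(dir, "art.csv"))
    readr::write_csv(run$importance, file.path(dir, "importance.csv"))
    for (nm in names(run$attributions)) {
      write_attributions(run$attributions[[nm]],
                         file.path(dir, paste0("attributions_", nm, ".csv")))
    }
    writeLines(
      jsonlite::toJSON(run$config, auto_unbox = TRUE, digits = NA),
      file.path(dir, "ranking_config.json")
    )
    return(invisible(dir))
  }
  if (inherits(run, "shapsel_selection")) {
    write_selection_trace(run$trace, file.path(dir, "trace"))
    write_eval_report(run$report, file.path(dir, "report.csv"))
    fold_plan_json(run$folds, file.path(dir, "folds.json"))
    return(invisible(dir))
  }
  abort("Unsupported artifact object.", class = "shapsel_config_error")
}
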