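#' Rank-guided optimized sequential forward selection
#'
#' A single guided pass over the ensemble average-rank order: the subset is
#' seeded with the top-ranked feature, then each next-ranked feature is
#' added in turn and kept only if the mean cross-validated accuracy
#' strictly improves (absolute tolerance `tol`; ties reject, preferring the
#' smaller subset).  After the pass, the top-ranked seed feature itself is
#' removed and the reduced subset re-scored — if that strictly improves,
#' the removal is kept.  This guided pass needs at most `M + 1` subset
#' evaluations, against the O(M^2) of classic sequential forward selection.
#'
#' One fixed fold plan is reused for every candidate so that comparisons
#' are paired; all seeds are recorded in the trace.
#'
#' @param data A [feature_table()] or data frame with encoded numeric
#'   features.
#' @param art An [ensemble_average_rank()] table covering all features of
#'   `data` (its row order is the candidate order).
#' @param clf A [classifier_spec()].
#' @param folds A [stratified_kfold_split()] plan for `data`.
#' @param smote A [smote_config()].
#' @param tol Strict-improvement tolerance (default `1e-12`).
#' @param label Label column name.
#' @return A `selection_trace`: fields `steps` (tibble: `feature`,
#'   `action` in `seed`/`accept`/`reject`/`removed_top`, `cv_score_with`,
#'   `cv_score_best_before`), `final_subset`, `final_score`,
#'   `n_evaluations`, `classifier_kind`, `seeds`.  `tidy()` returns the
#'   step log, `glance()` a one-row summary.
#' @export
optimized_forward_selection <- function(data, art, clf, folds,
                                        smote = smote_config(),
                                        tol = 1e-12, label = "label") {
  ft <- as_feature_table(data, label)
  feats <- ft_feature_names(ft)
  order_feats <- as.character(art$feature)
  if (!setequal(order_feats, feats)) {
    abort("The average-rank table must cover exactly the data's features.",
          class = "shapsel_config_error")
  }
  n_eval <- 0L
  score <- function(subset) {
    n_eval <<- n_eval + 1L
    evaluate_subset(ft, subset, clf, folds, smote, label)
  }
  top <- order_feats[1L]
  best <- score(top)
  subset <- top
  steps <- list(tibble(feature = top, action = "seed",
                       cv_score_with = best,
                       cv_score_best_before = NA_real_))
  for (f in order_feats[-1L]) {
    cand <- c(subset, f)
    s <- score(cand)
    if (s > best + tol) {
      steps <- c(steps, list(tibble(feature = f, action = "accept",
                                    cv_score_with = s,
                                    cv_score_best_before = best)))
      subset <- cand
      best <- s
    } else {
      steps <- c(steps, list(tibble(feature = f, action = "reject",
                                    cv_score_with = s,
                                    cv_score_best_before = best)))
    }
  }
  # Validate the seed: does dropping the top-ranked feature help?
  if (length(subset) > 1L) {
    reduced <- setdiff(subset, top)
    s <- score(reduced)
    if (s > best + tol) {
      steps <- c(steps, list(tibble(feature = top, action = "removed_top",
                                    cv_score_with = s,
                                    cv_score_best_before = best)))
      subset <- reduced
      best <- s
    }
  }
  structure(
    list(
      steps = bind_rows(steps),
      final_subset = subset,
      final_score = best,
      n_evaluations = n_eval,
      classifier_kind = clf$kind,
      seeds = list(folds = attr(folds, "seed"), smote = smote$seed,
                   model = clf$seed)
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", x$classifier_kind, ": ",
      length(x$final_subset), " feature(s) selected, CV accuracy ",
      sprintf("%.4f", x$final_score), " (", x$n_evaluations,
      " subset evaluations)\n", sep = "")
  cat("  subset:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  x$steps
}

#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) {
  tibble(
    n_selected = length(x$final_subset),
    final_score = x$final_score,
    n_evaluations = x$n_evaluations,
    classifier = x$classifier_kind
  )
}

#' Write a selection trace
#'
#' Writes the trace as JSON plus a human-readable log (one line per step)
#' and the final subset as a plain feature-name list.
#'
#' @param trace A `selection_trace`.
#' @param path Base path: `<path>.json`, `<path>.log`, and
#'   `<path>_subset.txt` are written.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  js <- jsonlite::toJSON(
    list(steps = trace$steps, final_subset = trace$final_subset,
         final_score = trace$final_score,
         n_evaluations = trace$n_evaluations,
         classifier = trace$classifier_kind, seeds = trace$seeds),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(js, paste0(path, ".json"))
  log_lines <- sprintf(
    "%-12s %-20s score_with=%.6f best_before=%s",
    trace$steps$action, trace$steps$feature, trace$steps$cv_score_with,
    ifelse(is.na(trace$steps$cv_score_best_before), "NA",
           sprintf("%.6f", trace$steps$cv_score_best_before))
  )
  writeLines(log_lines, paste0(path, ".log"))
  writeLines(trace$final_subset, paste0(path, "_subset.txt"))
  invisible(path)
}
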