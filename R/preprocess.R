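#' Preprocessing records
#'
#' Deterministic preprocessing steps attach a record of what they did as the
#' `"prep_record"` attribute of their result; `prep_record()` retrieves it.
#' The record is a plain list (serialisable to JSON with
#' [jsonlite::toJSON()]) holding, depending on the step,
#' `dropped_case_count`, per-feature `encoding_maps`, and the fitted
#' per-feature `feature_min` / `feature_max`.
#'
#' @param x Result of a preprocessing step.
#' @return A list, or `NULL` if `x` carries no record.
#' @export
prep_record <- function(x) {
  attr(x, "prep_record")
}

set_prep_record <- function(x, record) {
  attr(x, "prep_record") <- record
  x
}

#' Drop cases with missing values
#'
#' Removes every row that contains at least one missing feature or label
#' cell.  Missing cases are excluded rather than imputed; no imputation of
#' any kind is offered.
#'
#' @param data A [feature_table()] or data frame.
#' @param label Label column name (used for plain data frames).
#' @return The table without incomplete cases; `prep_record()` holds
#'   `dropped_case_count`.
#' @export
drop_missing_cases <- function(data, label = "label") {
  ft <- as_feature_table(data, label)
  keep <- stats::complete.cases(as_tibble(ft))
  if (!any(keep)) {
    abort("All cases contain missing values; nothing left to analyse.",
          class = "shapsel_data_error")
  }
  out <- rebuild_ft(as_tibble(ft)[keep, , drop = FALSE], ft)
  set_prep_record(out, list(dropped_case_count = sum(!keep)))
}

#' Label-encode categorical features
#'
#' Maps each categorical feature's distinct observed values to consecutive
#' integers `0..k-1`.  Values are ordered lexicographically on their string
#' form, which makes the encoding deterministic and platform independent
#' (no hash-order dependence).  Numeric features are untouched.
#'
#' @inheritParams drop_missing_cases
#' @return The encoded table; `prep_record()` holds `encoding_maps`, a named
#'   list of value-to-integer maps for every encoded feature.
#' @export
label_encode <- function(data, label = "label") {
  ft <- as_feature_table(data, label)
  flags <- ft_categorical(ft)
  tbl <- as_tibble(ft)
  maps <- list()
  for (f in names(flags)[flags]) {
    col <- tbl[[f]]
    if (is.numeric(col)) next
    vals <- sort(unique(as.character(col[!is.na(col)])), method = "radix")
    map <- stats::setNames(seq_along(vals) - 1L, vals)
    tbl[[f]] <- as.numeric(map[as.character(col)])
    maps[[f]] <- map
  }
  out <- rebuild_ft(tbl, ft, categorical = flags)
  set_prep_record(out, list(encoding_maps = maps))
}

#' Fit min-max normalisation bounds
#'
#' Records each feature's minimum and maximum on the supplied (training)
#' table.  Bounds are always fitted on training data only and then applied
#' to held-out data, so no information leaks from test folds.
#'
#' @inheritParams drop_missing_cases
#' @return A list with `feature_min` and `feature_max` (named numeric
#'   vectors), of class `minmax_record`.
#' @export
minmax_fit <- function(data, label = "label") {
  ft <- as_feature_table(data, label)
  x <- ft_matrix(ft)
  structure(
    list(
      feature_min = apply(x, 2, min, na.rm = TRUE),
      feature_max = apply(x, 2, max, na.rm = TRUE)
    ),
    class = "minmax_record"
  )
}

#' Min-max normalise features
#'
#' Rescales each feature value `x` to `(x - min(X)) / (max(X) - min(X))`
#' using bounds fitted on `train`.  Training values land in `[0, 1]`;
#' held-out values may fall outside and are deliberately not clipped (the
#' map is affine).  A constant training feature (`min == max`) maps every
#' value to 0.
#'
#' @param train Table the bounds are fitted on, or a [minmax_fit()] record.
#' @param apply_to Table to transform; defaults to `train`.
#' @param label Label column name.
#' @return The transformed `apply_to` table; `prep_record()` holds the
#'   fitted bounds.
#' @export
minmax_normalize <- function(train, apply_to = NULL, label = "label") {
  if (inherits(train, "minmax_record")) {
    rec <- train
    if (is.null(apply_to)) {
      abort("`apply_to` is required when `train` is a fitted record.",
            class = "shapsel_config_error")
    }
  } else {
    rec <- minmax_fit(train, label)
    if (is.null(apply_to)) apply_to <- train
  }
  ft <- as_feature_table(apply_to, label)
  feats <- ft_feature_names(ft)
  if (!setequal(feats, names(rec$feature_min))) {
    abort("Feature schema of `apply_to` does not match the fitted bounds.",
          class = "shapsel_config_error")
  }
  tbl <- as_tibble(ft)
  for (f in feats) {
    lo <- rec$feature_min[[f]]
    hi <- rec$feature_max[[f]]
    rng <- hi - lo
    tbl[[f]] <- if (rng == 0) rep(0, nrow(tbl)) else (tbl[[f]] - lo) / rng
  }
  out <- rebuild_ft(tbl, ft)
  set_prep_record(out, list(feature_min = rec$feature_min,
                            feature_max = rec$feature_max))
}

#' Standard preparation of a raw table
#'
#' Convenience composition of the deterministic steps: drop incomplete
#' cases, then label-encode categoricals.  (Normalisation is fold-local and
#' therefore lives inside the evaluation pipeline, not here.)
#'
#' @inheritParams drop_missing_cases
#' @return The prepared table with a combined `prep_record()`.
#' @export
prepare_dataset <- function(data, label = "label") {
  dropped <- drop_missing_cases(data, label)
  encoded <- label_encode(dropped, label)
  set_prep_record(encoded, c(prep_record(dropped), prep_record(encoded)))
}
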