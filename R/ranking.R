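#' Ranks from importance scores
#'
#' Sorts features by descending importance and assigns ranks, rank 1 being
#' the most important.  Ties are broken by original feature order (stable
#' sort), so equal scores keep the dataset's column order.
#'
#' @param importance Numeric importance vector, or the tibble returned by
#'   [global_importance()].
#' @param feature_names Feature names (taken from the tibble/names when
#'   omitted).
#' @return Named integer rank vector — a permutation of `1..M` in the
#'   original feature order.
#' @export
rank_from_importance <- function(importance, feature_names = NULL) {
  if (is.data.frame(importance)) {
    feature_names <- feature_names %||% importance$feature
    importance <- importance$importance
  }
  feature_names <- feature_names %||% names(importance) %||%
    paste0("f", seq_along(importance))
  if (length(importance) != length(feature_names)) {
    abort("`importance` and `feature_names` lengths differ.",
          class = "shapsel_config_error")
  }
  bad <- which(is.na(importance) | is.nan(importance))
  if (length(bad) > 0L) {
    abort(paste0("Importance is NaN/NA for feature(s): ",
                 paste(feature_names[bad], collapse = ", ")),
          class = "shapsel_numeric_error")
  }
  ord <- order(-importance)          # radix sort: stable, ties keep order
  ranks <- integer(length(importance))
  ranks[ord] <- seq_along(importance)
  stats::setNames(ranks, feature_names)
}

#' Build a feature rank table (FRT)
#'
#' Assembles the per-method rank vectors of the three ranking classifiers
#' into one table: a feature-name column followed by one integer rank
#' column per method.  Rank vectors given in a different feature order are
#' aligned by name.
#'
#' @param rank_vectors List of named integer rank vectors (one per
#'   method), each a permutation of `1..M`.
#' @param feature_names Feature order of the output rows (the dataset's
#'   column order); defaults to the names of the first vector.
#' @param method_names Column labels; default `names(rank_vectors)` or
#'   `method_1..`.
#' @return A tibble of class `shapsel_frt`: `feature` plus one rank column
#'   per method.
#' @export
build_frt <- function(rank_vectors, feature_names = NULL,
                      method_names = NULL) {
  stopifnot(is.list(rank_vectors), length(rank_vectors) >= 1L)
  feature_names <- feature_names %||% names(rank_vectors[[1L]])
  if (is.null(feature_names)) {
    abort("Feature names are required (named rank vectors or explicit).",
          class = "shapsel_config_error")
  }
  M <- length(feature_names)
  method_names <- method_names %||% names(rank_vectors) %||%
    paste0("method_", seq_along(rank_vectors))
  cols <- map(seq_along(rank_vectors), function(i) {
    rv <- rank_vectors[[i]]
    if (length(rv) != M) {
      abort("All rank vectors must cover every feature.",
            class = "shapsel_config_error")
    }
    if (!is.null(names(rv))) {
      if (!setequal(names(rv), feature_names)) {
        abort("Rank vector names do not match `feature_names`.",
              class = "shapsel_config_error")
      }
      rv <- rv[feature_names]
    }
    rv <- as.integer(rv)
    if (!identical(sort(rv), seq_len(M))) {
      abort(paste0("Rank column '", method_names[i],
                   "' is not a permutation of 1..", M, "."),
            class = "shapsel_integrity_error")
    }
    rv
  })
  out <- tibble(feature = feature_names)
  for (i in seq_along(cols)) out[[method_names[i]]] <- cols[[i]]
  structure(out, class = c("shapsel_frt", class(tibble())))
}

#' Ensemble average-rank table (ART)
#'
#' Adds the arithmetic mean of the per-method ranks as an `avg` column and
#' sorts the rows by it in ascending order, so the consensus-most-important
#' features come first.  Ties on `avg` are broken by the FRT row order —
#' i.e. the dataset's original column order.
#'
#' @param frt A [build_frt()] table (feature column + rank columns).
#' @return A tibble of class `shapsel_art`: the FRT columns plus `avg`,
#'   sorted ascending by `avg`.
#' @export
ensemble_average_rank <- function(frt) {
  frt <- validate_frt(frt)
  rank_cols <- setdiff(names(frt), "feature")
  avg <- rowMeans(as.matrix(as_tibble(frt)[rank_cols]))
  out <- as_tibble(frt)
  out$avg <- avg
  out <- out[order(avg), , drop = FALSE]   # stable: ties keep row order
  structure(out, class = c("shapsel_art", class(tibble())))
}

validate_frt <- function(frt) {
  if (!is.data.frame(frt) || !"feature" %in% names(frt)) {
    abort("An FRT must be a data frame with a `feature` column.",
          class = "shapsel_config_error")
  }
  rank_cols <- setdiff(names(frt), c("feature", "avg"))
  M <- nrow(frt)
  for (cn in rank_cols) {
    if (!identical(sort(as.integer(frt[[cn]])), seq_len(M))) {
      abort(paste0("Rank column '", cn, "' is not a permutation of 1..",
                   M, "."),
            class = "shapsel_integrity_error")
    }
  }
  frt[c("feature", rank_cols)]
}

#' Export rank tables as CSV
#'
#' Writes an FRT or ART in the conventional layout (feature, one column per
#' method, and for an ART the `avg` column formatted to six decimals).
#'
#' @param x A `shapsel_frt` or `shapsel_art` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(x, path) {
  out <- as_tibble(x)
  if ("avg" %in% names(out)) {
    out$avg <- sprintf("%.6f", out$avg)
  }
  readr::write_csv(out, path)
  invisible(path)
}
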