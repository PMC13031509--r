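#' Stratified k-fold split
#'
#' Assigns every case to one of `k` folds so that fold sizes differ by at
#' most one and each fold's class counts are within one case of exact
#' proportionality (the floor/ceiling of the class count divided by `k`).
#' The assignment is deterministic given `seed`.
#'
#' @param data A [feature_table()] or data frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the shuffle.
#' @param label Label column name.
#' @return A `fold_plan`: tibble with columns `row` and `fold` (folds are
#'   `1..k`), with attributes `k` and `seed`.
#' @export
stratified_kfold_split <- function(data, k = 10, seed = 1, label = "label") {
  ft <- as_feature_table(data, label)
  y <- ft_labels(ft)
  if (anyNA(y)) {
    abort("Labels contain missing values; drop incomplete cases first.",
          class = "shapsel_data_error")
  }
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < k)) {
    short <- names(counts)[counts < k]
    abort(
      paste0("Class ", paste(short, collapse = ", "), " has fewer than k = ",
             k, " members; stratified splitting impossible."),
      class = "shapsel_data_error"
    )
  }
  fold <- integer(length(y))
  with_seed(seed, {
    classes <- sort(unique(y))
    for (ci in seq_along(classes)) {
      idx <- which(y == classes[ci])
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      base <- n_c %/% k
      extra <- n_c %% k
      # base cases per fold; the remainder goes to the first `extra` folds
      # for one class and the last `extra` folds for the other, so total
      # fold sizes still differ by at most one.
      per_fold <- rep(base, k)
      if (extra > 0L) {
        extra_folds <- if (ci %% 2L == 1L) seq_len(extra) else k + 1L - seq_len(extra)
        per_fold[extra_folds] <- per_fold[extra_folds] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = per_fold)
    }
  })
  structure(
    tibble(row = seq_along(y), fold = fold),
    k = as.integer(k), seed = as.integer(seed),
    class = c("fold_plan", class(tibble()))
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("# A fold_plan: ", nrow(x), " cases in k = ", attr(x, "k"),
      " folds (seed ", attr(x, "seed"), ")\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Serialise a fold plan to JSON
#'
#' @param plan A `fold_plan`.
#' @param path Optional path; if given the JSON is written there.
#' @return JSON string (invisibly if written to file).
#' @export
fold_plan_json <- function(plan, path = NULL) {
  obj <- list(k = attr(plan, "k"), seed = attr(plan, "seed"),
              fold = plan$fold)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbours considered when
#'   interpolating (default 5, the standard choice).
#' @param seed Integer seed.
#' @return A `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5, seed = 1) {
  if (k_neighbors < 1) {
    abort("`k_neighbors` must be at least 1.", class = "shapsel_config_error")
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' SMOTE minority oversampling
#'
#' Raises the minority class to the majority count by interpolating between
#' minority cases and their nearest minority neighbours: each synthetic case
#' is `a + lambda * (b - a)` for an anchor `a`, one of its `k_neighbors`
#' nearest minority neighbours `b` (Euclidean distance on the supplied
#' representation), and `lambda` uniform on `[0, 1)`.  Anchors cycle
#' round-robin through the minority rows until the deficit is filled.
#' Original rows are preserved verbatim and the majority class is never
#' touched.  Apply to training folds only: oversampling before splitting
#' leaks synthetic copies of test cases into training.
#'
#' @param data A [feature_table()] or data frame with encoded numeric
#'   features.
#' @param config A [smote_config()].
#' @param label Label column name.
#' @return The augmented table; attribute `"synthetic"` is a logical vector
#'   tagging the appended synthetic rows.
#' @export
smote_oversample <- function(data, config = smote_config(), label = "label") {
  ft <- as_feature_table(data, label)
  y <- ft_labels(ft)
  x <- ft_matrix(ft)
  counts <- table(factor(y, levels = c(0, 1)))
  if (counts[["0"]] == counts[["1"]]) {
    out <- rebuild_ft(as_tibble(ft), ft)
    attr(out, "synthetic") <- rep(FALSE, nrow(out))
    return(out)
  }
  minority <- if (counts[["0"]] < counts[["1"]]) 0 else 1
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min < 2L) {
    abort("SMOTE needs at least 2 minority cases.",
          class = "shapsel_data_error")
  }
  k <- config$k_neighbors
  if (k >= n_min) {
    k <- n_min - 1L
    warn(paste0("k_neighbors reduced to ", k,
                " (minority class has only ", n_min, " cases)."))
  }
  deficit <- max(counts) - n_min
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  # k nearest minority neighbours of each minority row, self excluded;
  # distance ties resolved by row order for determinism.
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  if (k == 1L) nn <- matrix(nn, ncol = 1L)
  synth <- matrix(NA_real_, nrow = deficit, ncol = ncol(x))
  with_seed(config$seed, {
    anchors <- rep_len(seq_len(n_min), deficit)
    for (s in seq_len(deficit)) {
      a <- anchors[s]
      b <- nn[a, sample.int(k, 1L)]
      lambda <- runif(1L)
      synth[s, ] <- xm[a, ] + lambda * (xm[b, ] - xm[a, ])
    }
  })
  colnames(synth) <- colnames(x)
  synth_tbl <- as_tibble(as.data.frame(synth))
  synth_tbl[[ft_label_col(ft)]] <- rep(minority, deficit)
  out_tbl <- bind_rows(as_tibble(ft), synth_tbl[names(as_tibble(ft))])
  out <- rebuild_ft(out_tbl, ft)
  attr(out, "synthetic") <- c(rep(FALSE, nrow(ft)), rep(TRUE, deficit))
  out
}
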