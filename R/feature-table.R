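#' Construct a feature table
#'
#' A feature table is the universal tabular carrier of the package: a tibble
#' of named feature columns plus one binary label column (1 = positive case,
#' e.g. a confirmed coronary-artery-disease diagnosis).  Non-numeric feature
#' columns are flagged categorical; `NA` marks missing cells.
#'
#' @param data A data frame with one column per feature and a label column.
#' @param label Name of the binary label column.  Default `"label"`.
#' @param categorical Optional logical vector (one per feature column)
#'   overriding the automatic categorical detection (non-numeric = categorical).
#' @return A tibble of class `feature_table` with attributes `label_col` and
#'   `categorical`.
#' @examples
#' ft <- feature_table(tibble::tibble(age = c(63, 41), sex = c(1, 0),
#'                                    label = c(1, 0)))
#' ft_feature_names(ft)
#' @export
feature_table <- function(data, label = "label", categorical = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "shapsel_config_error")
  }
  data <- as_tibble(data)
  if (!label %in% names(data)) {
    abort(
      paste0("Label column '", label, "' not found in the data."),
      class = "shapsel_config_error"
    )
  }
  feats <- setdiff(names(data), label)
  if (length(feats) == 0L) {
    abort("At least one feature column is required.",
          class = "shapsel_config_error")
  }
  if (anyDuplicated(names(data))) {
    abort("Column names must be unique.", class = "shapsel_format_error")
  }
  lab <- data[[label]]
  lab_chr <- as.character(lab)
  ok <- is.na(lab_chr) | lab_chr %in% c("0", "1")
  if (!all(ok)) {
    bad <- unique(lab_chr[!ok])
    abort(
      paste0("Label column '", label, "' must be binary 0/1; found value(s): ",
             paste(utils::head(bad, 5L), collapse = ", ")),
      class = "shapsel_format_error"
    )
  }
  data[[label]] <- as.numeric(lab_chr)
  if (is.null(categorical)) {
    categorical <- vapply(data[feats], function(col) !is.numeric(col), logical(1))
  } else {
    if (length(categorical) != length(feats)) {
      abort("`categorical` must have one entry per feature column.",
            class = "shapsel_config_error")
    }
    categorical <- stats::setNames(as.logical(categorical), feats)
  }
  new_feature_table(data, label, categorical)
}

new_feature_table <- function(data, label_col, categorical) {
  structure(
    data,
    label_col = label_col,
    categorical = categorical,
    class = c("feature_table", class(as_tibble(data)))
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("# A feature_table: ", nrow(x), " cases x ", length(ft_feature_names(x)),
      " features (label: '", ft_label_col(x), "', positives: ",
      sum(ft_labels(x) == 1, na.rm = TRUE), ")\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Accessors for feature tables
#'
#' @param x A `feature_table` (or any data frame plus a `label` argument).
#' @param label Label column name, used when `x` carries no `label_col`
#'   attribute.
#' @return `ft_feature_names()` the feature column names; `ft_labels()` the
#'   numeric 0/1 label vector; `ft_features()` the feature columns as a
#'   tibble; `ft_matrix()` the features as a numeric matrix;
#'   `ft_categorical()` the named logical categorical flags; `ft_label_col()`
#'   the label column name.
#' @name feature-table-accessors
NULL

#' @rdname feature-table-accessors
#' @export
ft_label_col <- function(x, label = "label") {
  attr(x, "label_col") %||% label
}

#' @rdname feature-table-accessors
#' @export
ft_feature_names <- function(x, label = "label") {
  setdiff(names(x), ft_label_col(x, label))
}

#' @rdname feature-table-accessors
#' @export
ft_labels <- function(x, label = "label") {
  as.numeric(x[[ft_label_col(x, label)]])
}

#' @rdname feature-table-accessors
#' @export
ft_features <- function(x, label = "label") {
  as_tibble(x)[ft_feature_names(x, label)]
}

#' @rdname feature-table-accessors
#' @export
ft_matrix <- function(x, label = "label") {
  feats <- ft_features(x, label)
  nonnum <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(nonnum) > 0L) {
    abort(
      paste0("Feature(s) not numeric (encode first): ",
             paste(nonnum, collapse = ", ")),
      class = "shapsel_config_error"
    )
  }
  as.matrix(feats)
}

#' @rdname feature-table-accessors
#' @export
ft_categorical <- function(x, label = "label") {
  flags <- attr(x, "categorical")
  if (is.null(flags)) {
    feats <- ft_features(x, label)
    flags <- vapply(feats, function(col) !is.numeric(col), logical(1))
  }
  flags
}

# Re-wrap a plain tibble as a feature_table, carrying flags from a template.
rebuild_ft <- function(data, template, categorical = NULL) {
  new_feature_table(
    as_tibble(data),
    ft_label_col(template),
    categorical %||% ft_categorical(template)
  )
}

as_feature_table <- function(data, label = "label") {
  if (inherits(data, "feature_table")) data else feature_table(data, label)
}

#' Read a delimited clinical dataset
#'
#' Reads a delimited text file with a header row into a [feature_table()].
#' Empty cells and (in the UCI dialect, the default) `"?"` are treated as
#' missing; any column that fails to parse as numeric is flagged categorical.
#'
#' @param path Path to the file.
#' @param label_column Name of the binary label column.
#' @param delimiter Field delimiter, default `","`.
#' @param na Strings treated as missing.  Default `c("", "NA", "?")`
#'   (the `"?"` follows the UCI heart-disease file convention).
#' @return A [feature_table()].
#' @export
read_delimited_dataset <- function(path, label_column = "label",
                                   delimiter = ",", na = c("", "NA", "?")) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "shapsel_config_error")
  }
  df <- suppressWarnings(readr::read_delim(
    path, delim = delimiter, na = na, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    ragged <- probs[grepl("columns", probs$expected), , drop = FALSE]
    if (nrow(ragged) > 0L) {
      abort(
        paste0("Ragged row in ", path, " at line ", ragged$row[1L] + 1L,
               " (expected ", ragged$expected[1L], ", got ",
               ragged$actual[1L], ")."),
        class = "shapsel_format_error"
      )
    }
  }
  if (!label_column %in% names(df)) {
    abort(
      paste0("Label column '", label_column, "' not present in ", path, "."),
      class = "shapsel_config_error"
    )
  }
  feature_table(df, label = label_column)
}

#' Write a feature table to a delimited file
#'
#' Writes in the same dialect [read_delimited_dataset()] reads, so that a
#' write/read round trip is lossless for encoded numeric tables.
#'
#' @param x A `feature_table` (or data frame).
#' @param path Output path.
#' @param delimiter Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_delimited_dataset <- function(x, path, delimiter = ",") {
  readr::write_delim(as_tibble(x), path, delim = delimiter, na = "")
  invisible(path)
}
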