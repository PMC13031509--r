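#' Classifier specification
#'
#' Describes one of the supported binary classifiers together with its
#' hyperparameters.  All model fitting is delegated to established
#' libraries; the package only standardises the interface (numeric feature
#' matrix in, positive-class probability out).
#'
#' Supported kinds and their backing implementations:
#' \describe{
#'   \item{`xgboost`}{gradient-boosted trees via \pkg{xgboost}
#'     (`max_depth`, `n_estimators`, `learning_rate`).}
#'   \item{`random_forest`}{\pkg{ranger} probability forest
#'     (`n_estimators`, `max_depth`, `max_features` = `"sqrt"`/`"log2"`).}
#'   \item{`svm`}{\pkg{e1071} RBF support-vector machine with Platt-scaled
#'     probabilities (`C`, `gamma`).}
#'   \item{`decision_tree`}{\pkg{rpart} (`max_depth`, `criterion` =
#'     `"gini"`/`"entropy"`).}
#'   \item{`logistic`}{`stats::glm` logistic regression (unpenalised).}
#'   \item{`knn`}{k-nearest neighbours (`n_neighbors`, `metric` =
#'     `"euclidean"`/`"manhattan"`); the vote fraction of positive
#'     neighbours is the probability.}
#'   \item{`mlp`}{single-hidden-layer perceptron via \pkg{nnet}
#'     (`hidden_size`, `max_iter`, `decay`).}
#' }
#'
#' @param kind One of the classifier kinds above.
#' @param params Named list of hyperparameters; unspecified ones take the
#'   defaults of [default_hyperparameters()].
#' @param seed Integer seed applied before every (stochastic) fit.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("xgboost", "random_forest", "svm",
                                     "decision_tree", "logistic", "knn",
                                     "mlp"),
                            params = list(), seed = 1) {
  kind <- match.arg(kind)
  defaults <- default_hyperparameters(kind)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown hyperparameter(s) for ", kind, ": ",
                 paste(unknown, collapse = ", ")),
          class = "shapsel_config_error")
  }
  structure(
    list(kind = kind, params = utils::modifyList(defaults, params),
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(lapply(x$params, paste, collapse = ",")),
              sep = " = ", collapse = ", ")
  cat("<classifier_spec> ", x$kind, " (", ps, "), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Default hyperparameters per classifier kind
#'
#' @param kind Classifier kind as in [classifier_spec()].
#' @return Named list of defaults.
#' @export
default_hyperparameters <- function(kind) {
  switch(kind,
    xgboost = list(max_depth = 5, n_estimators = 40, learning_rate = 0.5),
    random_forest = list(n_estimators = 50, max_depth = 5,
                         max_features = "log2"),
    svm = list(C = 20, gamma = 0.1),
    decision_tree = list(max_depth = 5, criterion = "entropy"),
    logistic = list(),
    knn = list(n_neighbors = 11, metric = "euclidean"),
    mlp = list(hidden_size = 50, max_iter = 200, decay = 1e-4),
    abort(paste0("Unknown classifier kind: ", kind),
          class = "shapsel_config_error")
  )
}

#' Tuned hyperparameter presets for the three benchmark cohorts
#'
#' Named presets of grid-search winners for the three public
#' coronary-artery-disease benchmark datasets commonly used with this
#' method family.  They are convenient starting points; [grid_search()]
#' re-tunes from scratch on any data.
#'
#' @param dataset `"zalizadeh"`, `"cleveland"`, or `"statlog"`.
#' @param seed Seed stored in each returned spec.
#' @return Named list of [classifier_spec()] objects, one per classifier
#'   kind.
#' @export
preset_hyperparameters <- function(dataset = c("cleveland", "zalizadeh",
                                               "statlog"), seed = 1) {
  dataset <- match.arg(dataset)
  p <- switch(dataset,
    zalizadeh = list(
      xgboost = list(max_depth = 10, n_estimators = 50, learning_rate = 1.0),
      random_forest = list(n_estimators = 150, max_depth = 10,
                           max_features = "log2"),
      svm = list(C = 30, gamma = 0.1),
      decision_tree = list(max_depth = 5, criterion = "gini"),
      logistic = list(),
      knn = list(n_neighbors = 5, metric = "euclidean"),
      mlp = list(hidden_size = 120, max_iter = 1000, decay = 1e-4)
    ),
    cleveland = list(
      xgboost = list(max_depth = 5, n_estimators = 40, learning_rate = 0.5),
      random_forest = list(n_estimators = 50, max_depth = 5,
                           max_features = "log2"),
      svm = list(C = 20, gamma = 0.1),
      decision_tree = list(max_depth = 5, criterion = "entropy"),
      logistic = list(),
      knn = list(n_neighbors = 11, metric = "euclidean"),
      mlp = list(hidden_size = 120, max_iter = 100, decay = 1e-4)
    ),
    statlog = list(
      xgboost = list(max_depth = 5, n_estimators = 20, learning_rate = 1.0),
      random_forest = list(n_estimators = 50, max_depth = 5,
                           max_features = "log2"),
      svm = list(C = 5, gamma = 10),
      decision_tree = list(max_depth = 10, criterion = "entropy"),
      logistic = list(),
      knn = list(n_neighbors = 11, metric = "manhattan"),
      mlp = list(hidden_size = 100, max_iter = 50, decay = 1e-4)
    )
  )
  imap(p, function(params, kind) classifier_spec(kind, params, seed = seed))
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()] .
#' @param x Numeric feature matrix (cases x features).
#' @param y Numeric 0/1 label vector; both classes must be present.
#' @return A `fitted_classifier` usable with [predict_prob()].
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to fit a classifier.",
          class = "shapsel_data_error")
  }
  p <- spec$params
  fit <- with_seed(spec$seed, switch(spec$kind,
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$learning_rate, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = p$n_estimators, verbose = 0
    ),
    random_forest = {
      mtry <- switch(as.character(p$max_features),
                     log2 = max(1L, floor(log2(ncol(x)))),
                     sqrt = max(1L, floor(sqrt(ncol(x)))),
                     max(1L, floor(sqrt(ncol(x)))))
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = p$n_estimators, max.depth = p$max_depth, mtry = mtry,
        probability = TRUE, seed = spec$seed, num.threads = 1
      )
    },
    svm = e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
      cost = p$C, gamma = p$gamma, probability = TRUE, scale = FALSE
    ),
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      split <- if (identical(p$criterion, "gini")) "gini" else "information"
      rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = split),
        control = rpart::rpart.control(maxdepth = p$max_depth, xval = 0,
                                       cp = 0.001)
      )
    },
    logistic = {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = binomial()))
    },
    knn = list(train_x = x, train_y = y,
               k = min(p$n_neighbors, nrow(x)), metric = p$metric),
    mlp = {
      nnet::nnet(
        x = x, y = y, size = p$hidden_size, maxit = p$max_iter,
        decay = p$decay, entropy = TRUE, trace = FALSE,
        MaxNWts = 100000
      )
    }
  ))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 feature_names = colnames(x)),
            class = "fitted_classifier")
}

#' Positive-class probability predictions
#'
#' @param object A `fitted_classifier` or a probability model made with
#'   [as_prob_model()].
#' @param newx Numeric matrix of cases to score.
#' @param ... Unused.
#' @return Numeric vector of P(positive class) in `[0, 1]`.
#' @export
predict_prob <- function(object, newx, ...) {
  UseMethod("predict_prob")
}

#' @export
predict_prob.fitted_classifier <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(object$feature_names) && !is.null(colnames(newx))) {
    newx <- newx[, object$feature_names, drop = FALSE]
  }
  switch(object$kind,
    xgboost = as.numeric(predict(object$fit,
                                 xgboost::xgb.DMatrix(newx, nthread = 1))),
    random_forest = {
      pr <- predict(object$fit, data = as.data.frame(newx),
                    num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    svm = {
      pr <- attr(predict(object$fit, newx, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    },
    decision_tree = {
      pr <- predict(object$fit, as.data.frame(newx), type = "prob")
      as.numeric(pr[, "1"])
    },
    logistic = {
      as.numeric(predict(object$fit, as.data.frame(newx), type = "response"))
    },
    knn = knn_prob(object$fit, newx),
    mlp = as.numeric(predict(object$fit, newx))
  )
}

# Hand-rolled k-NN probability so the Manhattan metric is supported with
# deterministic distance-tie handling (ties resolved by training-row order).
knn_prob <- function(fit, newx) {
  tx <- fit$train_x
  k <- fit$k
  apply(newx, 1L, function(row) {
    d <- if (identical(fit$metric, "manhattan")) {
      colSums(abs(t(tx) - row))
    } else {
      sqrt(colSums((t(tx) - row)^2))
    }
    mean(fit$train_y[order(d)[seq_len(k)]])
  })
}

#' Wrap a probability function as a model
#'
#' Wraps `fun` (numeric matrix in, probability vector out) so it can be used
#' wherever a fitted classifier is expected — handy for closed-form models
#' in examples and oracle tests.
#'
#' @param fun Function taking a numeric matrix and returning a numeric
#'   vector of probabilities.
#' @return A `prob_model`.
#' @export
as_prob_model <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(fun = fun), class = "prob_model")
}

#' @export
predict_prob.prob_model <- function(object, newx, ...) {
  as.numeric(object$fun(as.matrix(newx)))
}
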