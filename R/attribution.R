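#' Value-function specification for Shapley attribution
#'
#' Defines the coalition value function `v(S)`: the model's positive-class
#' probability, marginalised over a background sample for the features
#' outside the coalition (interventional expectation).  `v(F)` is the
#' probability on the instance itself, and `v(emptyset)` is the mean
#' probability over the background — the base value `phi0`.
#'
#' @param background Numeric matrix (or [feature_table()]) of reference
#'   cases.  If it has more than `max_background` rows, a seeded subsample
#'   of that size is taken.
#' @param max_background Cap on background rows (default 100).
#' @param seed Seed for the background subsample.
#' @param label Label column name when `background` is a feature table.
#' @return A `value_function_spec`.
#' @export
value_function_spec <- function(background, max_background = 100, seed = 1,
                                label = "label") {
  if (inherits(background, "feature_table") || is.data.frame(background)) {
    lc <- ft_label_col(background, label)
    bg <- if (lc %in% names(background)) {
      ft_matrix(as_feature_table(background, label))
    } else {
      as.matrix(background)
    }
  } else {
    bg <- as.matrix(background)
  }
  if (nrow(bg) == 0L) {
    abort("Background sample must be non-empty.",
          class = "shapsel_config_error")
  }
  if (max_background < 1) {
    abort("`max_background` must be at least 1.",
          class = "shapsel_config_error")
  }
  if (nrow(bg) > max_background) {
    keep <- with_seed(seed, sample.int(nrow(bg), max_background))
    bg <- bg[keep, , drop = FALSE]
  }
  structure(list(background = bg, output = "positive_class_probability",
                 max_background = as.integer(max_background),
                 seed = as.integer(seed)),
            class = "value_function_spec")
}

# Evaluate v(S) for every coalition (row of the logical mask matrix `Z`)
# and every instance (row of `X`), in one batched prediction per coalition.
# Returns a C x I matrix of coalition values.
eval_coalition_values <- function(model, X, Z, vf) {
  X <- as.matrix(X)
  bg <- vf$background
  B <- nrow(bg)
  I <- nrow(X)
  C <- nrow(Z)
  V <- matrix(NA_real_, nrow = C, ncol = I)
  bg_rep <- bg[rep(seq_len(B), times = I), , drop = FALSE]
  inst_rep_idx <- rep(seq_len(I), each = B)
  for (ci in seq_len(C)) {
    present <- which(Z[ci, ])
    hybrid <- bg_rep
    if (length(present) > 0L) {
      hybrid[, present] <- X[inst_rep_idx, present, drop = FALSE]
    }
    colnames(hybrid) <- colnames(bg)
    preds <- predict_prob(model, hybrid)
    V[ci, ] <- colMeans(matrix(preds, nrow = B, ncol = I))
  }
  V
}

#' Coalition value v(S)
#'
#' The model's expected positive-class probability when the coalition's
#' features take their values from `instance` and all remaining features
#' are drawn from the background sample (averaged over background rows).
#'
#' @param model A fitted classifier or [as_prob_model()] object.
#' @param instance Numeric feature vector.
#' @param coalition Integer vector of feature indices present (possibly
#'   empty).
#' @param vf A [value_function_spec()].
#' @return A single number in `[0, 1]`.
#' @export
coalition_value <- function(model, instance, coalition, vf) {
  stopifnot(inherits(vf, "value_function_spec"))
  M <- ncol(vf$background)
  instance <- as.numeric(instance)
  if (length(instance) != M) {
    abort("`instance` length must match the background feature count.",
          class = "shapsel_config_error")
  }
  coalition <- as.integer(coalition)
  if (length(coalition) > 0L && (min(coalition) < 1L || max(coalition) > M)) {
    abort("Coalition indices must lie in 1..M.",
          class = "shapsel_config_error")
  }
  z <- matrix(FALSE, nrow = 1L, ncol = M)
  z[1L, coalition] <- TRUE
  X <- matrix(instance, nrow = 1L)
  colnames(X) <- colnames(vf$background)
  eval_coalition_values(model, X, z, vf)[1L, 1L]
}

shapley_subset_weight <- function(s, M) {
  # |S|! (M - |S| - 1)! / M!  computed in log space for stability
  exp(lgamma(s + 1) + lgamma(M - s) - lgamma(M + 1))
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Computes, for one instance, the exact Shapley value of every feature:
#' `phi_i = sum over S not containing i of |S|!(M-|S|-1)!/M! *
#' (v(S + i) - v(S))`, with `v` the background-marginalised probability of
#' [value_function_spec()].  All `2^M` coalitions are enumerated, so `M`
#' is capped at 15; use [sampled_shapley()] above that.
#'
#' @inheritParams coalition_value
#' @return Numeric attribution vector of length `M`, with attribute
#'   `"base_value"` = `v(emptyset)`.
#' @export
exact_shapley <- function(model, instance, vf) {
  stopifnot(inherits(vf, "value_function_spec"))
  M <- ncol(vf$background)
  if (M > 15L) {
    abort(paste0("Exact enumeration is limited to M <= 15 features (got ",
                 M, "); use sampled_shapley()."),
          class = "shapsel_size_error")
  }
  Z <- all_coalitions(M)
  X <- matrix(as.numeric(instance), nrow = 1L)
  colnames(X) <- colnames(vf$background)
  v <- eval_coalition_values(model, X, Z, vf)[, 1L]
  sizes <- rowSums(Z)
  phi <- numeric(M)
  # coalition row index is the bitmask value + 1, so S + {i} is a bit flip
  for (i in seq_len(M)) {
    without_i <- which(!Z[, i])
    with_i <- without_i + 2^(i - 1L)
    w <- shapley_subset_weight(sizes[without_i], M)
    phi[i] <- sum(w * (v[with_i] - v[without_i]))
  }
  names(phi) <- colnames(vf$background)
  attr(phi, "base_value") <- v[1L]   # empty coalition
  phi
}

# All 2^M coalitions as a logical matrix ordered by bitmask value, so row
# b+1 is the subset whose bits are set in b.
all_coalitions <- function(M) {
  b <- 0:(2^M - 1)
  Z <- matrix(FALSE, nrow = length(b), ncol = M)
  for (i in seq_len(M)) {
    Z[, i] <- bitwAnd(b, 2^(i - 1L)) > 0L
  }
  Z
}

kernel_weight <- function(s, M) {
  # KernelSHAP weight for one coalition of size s (0 < s < M)
  (M - 1) / (choose(M, s) * s * (M - s))
}

#' Coalition-sampling Shapley attribution (KernelSHAP)
#'
#' Approximates Shapley values for many instances at once by solving the
#' kernel-weighted least-squares coalition regression, with the efficiency
#' constraint (attributions sum to `v(F) - v(emptyset)`) enforced exactly.
#' When `n_coalitions >= 2^M - 2` the full non-trivial coalition set is
#' enumerated with exact kernel weights, in which case the solution equals
#' [exact_shapley()] up to numerical error.
#'
#' @param model A fitted classifier or [as_prob_model()] object.
#' @param instances Numeric matrix or [feature_table()] of instances to
#'   explain.
#' @param vf A [value_function_spec()].
#' @param n_coalitions Number of sampled coalitions (at least `2M + 2`).
#' @param seed Integer seed for coalition sampling.
#' @param label Label column name when `instances` is a feature table.
#' @return An [attribution_matrix()].
#' @export
sampled_shapley <- function(model, instances, vf, n_coalitions = NULL,
                            seed = 1, label = "label") {
  stopifnot(inherits(vf, "value_function_spec"))
  M <- ncol(vf$background)
  X <- if (is.data.frame(instances)) {
    ft <- as_feature_table(instances, label)
    ft_matrix(ft)
  } else {
    as.matrix(instances)
  }
  if (ncol(X) != M) {
    abort("Instance feature count must match the background.",
          class = "shapsel_config_error")
  }
  if (M == 1L) {
    # single feature: efficiency determines the attribution outright
    Ztriv <- rbind(FALSE, TRUE)
    Vtriv <- eval_coalition_values(model, X, Ztriv, vf)
    phi <- matrix(Vtriv[2L, ] - Vtriv[1L, ], ncol = 1L,
                  dimnames = list(NULL, colnames(vf$background)))
    return(attribution_matrix(phi, base_value = mean(Vtriv[1L, ]),
                              method = "exact",
                              base_values = Vtriv[1L, ]))
  }
  n_coalitions <- n_coalitions %||% min(2^M - 2, max(2 * M + 2, 10 * M))
  if (n_coalitions < min(2 * M + 2, 2^M - 2)) {
    abort("`n_coalitions` must be at least 2M + 2 (or the full 2^M - 2).",
          class = "shapsel_config_error")
  }
  full_enum <- n_coalitions >= 2^M - 2
  if (full_enum) {
    Z <- all_coalitions(M)
    Z <- Z[rowSums(Z) > 0 & rowSums(Z) < M, , drop = FALSE]
    w <- kernel_weight(rowSums(Z), M)
  } else {
    samp <- sample_kernel_coalitions(M, n_coalitions, seed)
    Z <- samp$Z
    w <- samp$w
  }
  # coalition values, plus the two trivial coalitions for the constraint
  Ztriv <- rbind(rep(FALSE, M), rep(TRUE, M))
  Vtriv <- eval_coalition_values(model, X, Ztriv, vf)
  v0 <- Vtriv[1L, ]
  vF <- Vtriv[2L, ]
  V <- eval_coalition_values(model, X, Z, vf)
  # Weighted least squares with the efficiency constraint eliminated into
  # the last coefficient: phi_M = (vF - v0) - sum(phi_[1..M-1]).
  Zn <- Z * 1
  A <- Zn[, -M, drop = FALSE] - Zn[, M]
  # response per instance: v(S) - v0 - z_M (vF - v0)
  Y <- V - matrix(v0, nrow(Z), length(v0), byrow = TRUE) -
    outer(Zn[, M], vF - v0)
  AtW <- t(A * w)
  G <- AtW %*% A
  phi_head <- tryCatch(
    solve(G, AtW %*% Y),
    error = function(e) {
      abort(paste0("Degenerate coalition design: ", conditionMessage(e)),
            class = "shapsel_numeric_error")
    }
  )
  phi_last <- (vF - v0) - colSums(phi_head)
  phi <- t(rbind(phi_head, phi_last))
  colnames(phi) <- colnames(vf$background)
  attribution_matrix(phi, base_value = mean(v0),
                     method = if (full_enum) "exact" else "sampling",
                     base_values = v0)
}

# Sample coalitions from the KernelSHAP weight distribution.  Coalitions
# are drawn in complementary pairs (S and its complement share the same
# kernel weight), duplicates are collapsed into frequency weights, and a
# degenerate draw (fewer than M distinct coalitions) is re-sampled with a
# derived seed and a warning.
sample_kernel_coalitions <- function(M, n_coalitions, seed) {
  sizes <- 1:(M - 1)
  size_prob <- (M - 1) / (sizes * (M - sizes))
  size_prob <- size_prob / sum(size_prob)
  attempt <- 0L
  repeat {
    Z <- with_seed(derive_seed(seed, attempt), {
      n_pairs <- ceiling(n_coalitions / 2)
      out <- matrix(FALSE, nrow = 2L * n_pairs, ncol = M)
      for (p in seq_len(n_pairs)) {
        s <- sample(sizes, 1L, prob = size_prob)
        idx <- sample.int(M, s)
        out[2L * p - 1L, idx] <- TRUE
        out[2L * p, -idx] <- TRUE
      }
      out[seq_len(n_coalitions), , drop = FALSE]
    })
    key <- apply(Z, 1L, paste, collapse = "")
    tab <- table(key)
    uniq <- !duplicated(key)
    Zu <- Z[uniq, , drop = FALSE]
    w <- as.numeric(tab[key[uniq]])
    if (nrow(Zu) >= M) {
      return(list(Z = Zu, w = w))
    }
    attempt <- attempt + 1L
    warn("Sampled coalition design was degenerate; resampling.")
    if (attempt > 25L) {
      abort("Could not sample a non-degenerate coalition design.",
            class = "shapsel_numeric_error")
    }
  }
}

#' Attribution matrix
#'
#' Per-instance, per-feature Shapley values for one fitted model, plus the
#' base value `phi0` (mean model probability over the background).
#'
#' @param values Numeric n x M matrix of attributions.
#' @param base_value Scalar `phi0`.
#' @param method `"exact"`, `"sampling"`, or `"delegated"`.
#' @param base_values Optional per-instance base values (identical to
#'   `base_value` for a fixed background; kept for audit).
#' @return An `attribution_matrix`.
#' @export
attribution_matrix <- function(values, base_value,
                               method = c("exact", "sampling", "delegated"),
                               base_values = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    abort("Attributions must be finite.", class = "shapsel_numeric_error")
  }
  structure(list(values = values, base_value = base_value, method = method,
                 base_values = base_values),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("<attribution_matrix> ", nrow(x$values), " instances x ",
      ncol(x$values), " features; method = ", x$method,
      "; base value = ", signif(x$base_value, 6), "\n", sep = "")
  invisible(x)
}

#' @method tidy attribution_matrix
#' @export
tidy.attribution_matrix <- function(x, ...) {
  vals <- as_tibble(as.data.frame(x$values))
  vals$instance <- seq_len(nrow(vals))
  tidyr::pivot_longer(vals, -"instance", names_to = "feature",
                      values_to = "phi")
}

#' Global feature importance from attributions
#'
#' The mean absolute Shapley value of each feature across instances — the
#' standard global importance summary used to rank features.
#'
#' @param a An [attribution_matrix()] (or bare numeric matrix).
#' @return A tibble with columns `feature` and `importance`, in the
#'   original feature order.
#' @export
global_importance <- function(a) {
  vals <- if (inherits(a, "attribution_matrix")) a$values else as.matrix(a)
  if (nrow(vals) < 1L) {
    abort("At least one instance is required.", class = "shapsel_data_error")
  }
  imp <- colMeans(abs(vals))
  tibble(
    feature = colnames(vals) %||% paste0("f", seq_along(imp)),
    importance = as.numeric(imp)
  )
}

#' Export an attribution matrix
#'
#' Writes the per-instance attributions as a wide CSV plus a JSON sidecar
#' holding the base value and method.
#'
#' @param a An [attribution_matrix()].
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(a, path) {
  stopifnot(inherits(a, "attribution_matrix"))
  df <- as_tibble(as.data.frame(a$values))
  df <- bind_cols(tibble(instance = seq_len(nrow(df))), df)
  readr::write_csv(df, path)
  sidecar <- jsonlite::toJSON(
    list(base_value = a$base_value, method = a$method),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(sidecar, paste0(path, ".json"))
  invisible(path)
}
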