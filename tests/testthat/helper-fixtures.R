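# Small deterministic fixtures shared across tests.  Everything is built in
# code; nothing is read from disk except the packaged reference rank tables.

as_tibble <- tibble::as_tibble

# Bare data-frame view for content comparisons: drops the bookkeeping
# attributes (label column, categorical flags, preprocessing records, role
# tags) that legitimately differ between pipeline stages.
bare_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  rownames(x) <- NULL
  x
}

tiny_table <- function() {
  tibble::tibble(
    age = c(63, 41, 55),
    sex = c(1, 0, 1),
    label = c(1, 0, 1)
  )
}

# A separable dataset: one binary feature equal to the label, plus noise.
separable_table <- function(n = 40, seed = 42) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  tibble::tibble(
    signal = y,
    junk1 = rnorm(n),
    junk2 = rnorm(n),
    label = y
  )
}

# Balanced pure-noise dataset (no feature carries signal).
noise_table <- function(n = 60, m = 3, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * m), n, m))
  names(x) <- paste0("noise", seq_len(m))
  x$label <- rep(c(0, 1), length.out = n)
  tibble::as_tibble(x)
}

linear_prob_model <- function(w, intercept = 0) {
  as_prob_model(function(X) as.numeric(intercept + X %*% w))
}

# Non-additive bounded model used for axiom checks.
interaction_model <- function(M) {
  as_prob_model(function(X) {
    z <- 0.6 * X[, 1] - 0.4 * X[, 2] + 0.5 * X[, 1] * X[, min(3, M)]
    if (M >= 4) z <- z + 0.3 * sin(X[, 4])
    plogis(z)
  })
}

std_background <- function(M, B = 20, seed = 7, names = NULL) {
  set.seed(seed)
  bg <- matrix(rnorm(B * M), B, M)
  colnames(bg) <- names %||% paste0("f", seq_len(M))
  bg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Shapley oracle: the average over all M! feature orderings of
# the marginal contribution of each feature, using coalition_value() only.
# Deliberately shares no code with the subset-weighting implementation.
permutation_shapley_oracle <- function(model, instance, vf) {
  M <- length(instance)
  perms <- gtools_permutations(M)
  phi <- numeric(M)
  for (p in seq_len(nrow(perms))) {
    ord <- perms[p, ]
    S <- integer(0)
    for (i in ord) {
      before <- coalition_value(model, instance, S, vf)
      after <- coalition_value(model, instance, c(S, i), vf)
      phi[i] <- phi[i] + (after - before)
      S <- c(S, i)
    }
  }
  phi / nrow(perms)
}

# All permutations of 1..n (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

ref_frt_path <- function() {
  system.file("extdata", "cleveland_frt.csv", package = "shapsel")
}

ref_art_path <- function() {
  system.file("extdata", "cleveland_art.csv", package = "shapsel")
}
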