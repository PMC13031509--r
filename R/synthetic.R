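#' Specification for a synthetic clinical-style dataset
#'
#' Describes a generated binary-outcome tabular dataset with planted ground
#' truth: informative features drive the label through a logistic link,
#' redundant features are noisy copies of informative parents, noise
#' features are independent, and a configurable share of columns is
#' dichotomised at its median to mimic clinical yes/no indicators.
#'
#' @param n Number of cases.
#' @param m_informative,m_redundant,m_noise Feature counts per role.
#' @param effect_sizes Logistic coefficients of the informative features
#'   (recycled to `m_informative`).
#' @param redundancy_rho Correlation of each redundant feature with its
#'   informative parent (parents cycle round-robin).
#' @param imbalance Expected positive-class fraction, in (0, 1).
#' @param noise_sd Standard deviation of Gaussian noise added to the linear
#'   predictor (label noise).
#' @param fraction_binary Share of feature columns dichotomised at their
#'   median.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 300, m_informative = 4, m_redundant = 4,
                           m_noise = 8, effect_sizes = c(2.5, 2, 1.5, 1.5),
                           redundancy_rho = 0.8, imbalance = 0.4,
                           noise_sd = 0.5, fraction_binary = 0.25,
                           seed = 1) {
  if (m_informative < 0 || m_redundant < 0 || m_noise < 0 ||
      m_informative + m_redundant + m_noise < 1) {
    abort("Feature counts must be non-negative with a positive total.",
          class = "shapsel_config_error")
  }
  if (imbalance <= 0 || imbalance >= 1) {
    abort("`imbalance` must lie strictly between 0 and 1.",
          class = "shapsel_config_error")
  }
  if (abs(redundancy_rho) > 1) {
    abort("`redundancy_rho` must lie in [-1, 1].",
          class = "shapsel_config_error")
  }
  if (m_redundant > 0 && m_informative == 0) {
    abort("Redundant features need informative parents.",
          class = "shapsel_config_error")
  }
  structure(
    list(n = as.integer(n), m_informative = as.integer(m_informative),
         m_redundant = as.integer(m_redundant), m_noise = as.integer(m_noise),
         effect_sizes = rep_len(as.numeric(effect_sizes),
                                max(m_informative, 1L))[seq_len(m_informative)],
         redundancy_rho = redundancy_rho, imbalance = imbalance,
         noise_sd = noise_sd, fraction_binary = fraction_binary,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Solve the logistic intercept so that mean(plogis(b0 + eta)) == target,
# by bisection to 1e-6.  mean(plogis(b0 + eta)) is increasing in b0.
solve_intercept <- function(eta, target, tol = 1e-6) {
  f <- function(b0) mean(plogis(b0 + eta)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Informative features are standard normal; the label is Bernoulli with
#' probability `plogis(b0 + X beta + e)`, where the intercept `b0` is
#' solved numerically (bisection to 1e-6) so the expected positive fraction
#' equals `imbalance`, and `e ~ N(0, noise_sd)`.  Each redundant feature is
#' `rho * parent + sqrt(1 - rho^2) * independent noise`; noise features are
#' independent standard normal.  A seeded sample of `fraction_binary` of
#' the columns is then dichotomised at its median.  Deterministic given the
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param exact_counts If `TRUE`, the positive count is made exactly
#'   `round(n * imbalance)` by thresholding the noisy linear predictor at
#'   its matching quantile instead of Bernoulli draws (used by the shape
#'   presets).
#' @return A list with `data` (a [feature_table()], label column `label`)
#'   and `roles` (tibble: `feature`, `role` in
#'   informative/redundant/noise, `binary` flag).
#' @export
synthesize_dataset <- function(spec, exact_counts = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    mi <- spec$m_informative; mr <- spec$m_redundant; mn <- spec$m_noise
    Xi <- matrix(rnorm(n * mi), n, mi)
    eta <- if (mi > 0) as.numeric(Xi %*% spec$effect_sizes) else rep(0, n)
    eta <- eta + rnorm(n, 0, spec$noise_sd)
    if (exact_counts) {
      n_pos <- round(n * spec$imbalance)
      # logistic residuals, then take the top n_pos of the latent score:
      # keeps the planted signal while pinning the class counts exactly.
      latent <- eta + stats::rlogis(n)
      y <- as.numeric(rank(-latent, ties.method = "first") <= n_pos)
    } else {
      b0 <- solve_intercept(eta, spec$imbalance)
      y <- rbinom(n, 1L, plogis(b0 + eta))
    }
    Xr <- if (mr > 0) {
      parents <- rep_len(seq_len(mi), mr)
      rho <- spec$redundancy_rho
      vapply(parents, function(p) {
        rho * Xi[, p] + sqrt(1 - rho^2) * rnorm(n)
      }, numeric(n))
    } else {
      matrix(numeric(0), n, 0)
    }
    Xn <- matrix(rnorm(n * mn), n, mn)
    X <- cbind(Xi, Xr, Xn)
    feature <- c(
      if (mi > 0) paste0("inf", seq_len(mi)),
      if (mr > 0) paste0("red", seq_len(mr)),
      if (mn > 0) paste0("noise", seq_len(mn))
    )
    colnames(X) <- feature
    role <- c(rep("informative", mi), rep("redundant", mr), rep("noise", mn))
    M <- ncol(X)
    n_bin <- round(spec$fraction_binary * M)
    bin_cols <- if (n_bin > 0) sort(sample.int(M, n_bin)) else integer(0)
    for (j in bin_cols) {
      X[, j] <- as.numeric(X[, j] > stats::median(X[, j]))
    }
    tbl <- as_tibble(as.data.frame(X))
    tbl$label <- y
    list(
      data = feature_table(tbl, label = "label"),
      roles = tibble(feature = feature, role = role,
                     binary = seq_len(M) %in% bin_cols)
    )
  })
}

#' The planted-recovery benchmark specification
#'
#' The fixed synthetic study condition used to test whether the full
#' ranking-and-selection pipeline recovers planted signal: 4 informative
#' features (effect sizes 2.5, 2, 1.5, 1.5), 4 redundant copies
#' (rho = 0.8), 8 pure-noise features, 600 cases, a 40% positive class,
#' moderate label noise, and a quarter of the columns dichotomised.
#'
#' @param seed Integer seed (varies the draw, not the condition).
#' @return A [synthetic_spec()].
#' @export
planted_recovery_spec <- function(seed = 1) {
  synthetic_spec(
    n = 600, m_informative = 4, m_redundant = 4, m_noise = 8,
    effect_sizes = c(2.5, 2, 1.5, 1.5), redundancy_rho = 0.8,
    imbalance = 0.4, noise_sd = 0.5, fraction_binary = 0.25, seed = seed
  )
}

#' Seeded fixtures shaped like the public CAD benchmarks
#'
#' Synthetic datasets matching the case/feature/class-count shape of the
#' three public coronary-artery-disease benchmark datasets, so the full
#' pipeline can be exercised without any download.  The content is
#' synthetic; only the shape (n, M, class counts) mirrors the benchmarks.
#'
#' @param preset `"zalizadeh_like"` (303 cases, 55 features, 216
#'   positives), `"cleveland_like"` (303 x 13, 139 positives), or
#'   `"statlog_like"` (270 x 13, 120 positives).
#' @param seed Integer seed.
#' @return A [feature_table()]; attribute `"roles"` carries the planted
#'   ground truth.
#' @export
make_cad_like_fixture <- function(preset = c("cleveland_like",
                                             "zalizadeh_like",
                                             "statlog_like"),
                                  seed = 20260101) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    zalizadeh_like = synthetic_spec(
      n = 303, m_informative = 8, m_redundant = 12, m_noise = 35,
      effect_sizes = c(2.5, 2.2, 2, 1.8, 1.6, 1.5, 1.5, 1.5),
      redundancy_rho = 0.7, imbalance = 216 / 303, noise_sd = 0.5,
      fraction_binary = 0.6, seed = derive_seed(seed, 1L)
    ),
    cleveland_like = synthetic_spec(
      n = 303, m_informative = 5, m_redundant = 3, m_noise = 5,
      effect_sizes = c(2.5, 2, 1.8, 1.5, 1.5), redundancy_rho = 0.7,
      imbalance = 139 / 303, noise_sd = 0.5, fraction_binary = 0.3,
      seed = derive_seed(seed, 2L)
    ),
    statlog_like = synthetic_spec(
      n = 270, m_informative = 5, m_redundant = 3, m_noise = 5,
      effect_sizes = c(2.5, 2, 1.8, 1.5, 1.5), redundancy_rho = 0.7,
      imbalance = 120 / 270, noise_sd = 0.5, fraction_binary = 0.3,
      seed = derive_seed(seed, 3L)
    )
  )
  out <- synthesize_dataset(spec, exact_counts = TRUE)
  ft <- out$data
  attr(ft, "roles") <- out$roles
  ft
}
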