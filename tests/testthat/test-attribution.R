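test_that("coalition value interpolates between base value and full prediction", {
  bg <- std_background(3, B = 15, seed = 2)
  vf <- value_function_spec(bg)
  f <- interaction_model(3)
  x <- c(0.8, -0.4, 1.2)
  # full coalition: the model's probability on the instance itself
  expect_equal(coalition_value(f, x, 1:3, vf),
               predict_prob(f, matrix(x, 1, 3)), tolerance = 1e-12)
  # empty coalition: mean probability over the background (phi0)
  expect_equal(coalition_value(f, x, integer(0), vf),
               mean(predict_prob(f, bg)), tolerance = 1e-12)
  # additive model, coalition {1}: w1 x1 + w2 mean_B(x2)
  g <- linear_prob_model(c(0.2, 0.3, 0))
  expect_equal(coalition_value(g, x, 1L, vf),
               0.2 * x[1] + 0.3 * mean(bg[, 2]), tolerance = 1e-12)
  expect_error(coalition_value(g, x, 5L, vf), class = "shapsel_config_error")
})

test_that("exact Shapley satisfies the dummy axiom and the linear closed form", {
  bg <- std_background(4, B = 25, seed = 3)
  vf <- value_function_spec(bg)
  x <- c(0.5, -1, 2, 0.3)
  # a model ignoring feature 4 gives it exactly zero attribution
  f <- as_prob_model(function(X) plogis(X[, 1] - 0.5 * X[, 2] * X[, 3]))
  phi <- exact_shapley(f, x, vf)
  expect_equal(unname(phi[4]), 0, tolerance = 1e-12)
  # linear model on any background: phi_i = w_i (x_i - mean_B(x_i))
  w <- c(0.15, -0.2, 0.05, 0.4)
  g <- linear_prob_model(w, intercept = 0.3)
  phig <- exact_shapley(g, x, vf)
  expect_equal(as.numeric(phig), w * (x - colMeans(bg)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("exact Shapley agrees with an independent permutation-enumeration oracle", {
  bg <- std_background(3, B = 10, seed = 5)
  vf <- value_function_spec(bg)
  f <- interaction_model(3)
  x <- c(1.1, 0.4, -0.7)
  phi <- exact_shapley(f, x, vf)
  oracle <- permutation_shapley_oracle(f, x, vf)
  expect_equal(as.numeric(phi), oracle, tolerance = 1e-9)
})

test_that("efficiency, symmetry and linearity hold for the exact method", {
  M <- 5
  bg <- std_background(M, B = 20, seed = 6)
  vf <- value_function_spec(bg)
  f <- interaction_model(M)
  set.seed(8)
  for (r in 1:4) {
    x <- rnorm(M)
    phi <- exact_shapley(f, x, vf)
    fx <- predict_prob(f, matrix(x, 1, M))
    expect_lt(abs(sum(phi) + attr(phi, "base_value") - fx), 1e-9)
  }
  # symmetry: a model symmetric in features 1 and 2, instance with x1 = x2,
  # background symmetric in those columns
  bg_sym <- bg
  bg_sym[, 2] <- bg_sym[, 1]
  vf_sym <- value_function_spec(bg_sym)
  h <- as_prob_model(function(X) plogis(X[, 1] + X[, 2] + 0.3 * X[, 3]))
  xs <- c(0.7, 0.7, -0.2, 0.1, 0.4)
  phis <- exact_shapley(h, xs, vf_sym)
  expect_lt(abs(phis[1] - phis[2]), 1e-9)
  # linearity: attributions of an average of two models = average of
  # attributions
  f1 <- as_prob_model(function(X) plogis(X[, 1] * X[, 2]))
  f2 <- as_prob_model(function(X) plogis(-X[, 3] + X[, 4]))
  favg <- as_prob_model(function(X) {
    (plogis(X[, 1] * X[, 2]) + plogis(-X[, 3] + X[, 4])) / 2
  })
  x <- c(0.3, -0.8, 1.2, 0.5, -0.1)
  pa <- exact_shapley(f1, x, vf)
  pb <- exact_shapley(f2, x, vf)
  pc <- exact_shapley(favg, x, vf)
  expect_equal(as.numeric(pc), as.numeric((pa + pb) / 2),
               tolerance = 1e-9)
})

test_that("the enumeration guard refuses M > 15", {
  bg <- std_background(16, B = 3, seed = 1)
  vf <- value_function_spec(bg)
  f <- linear_prob_model(rep(0.01, 16))
  expect_error(exact_shapley(f, rnorm(16), vf), "sampled_shapley",
               class = "shapsel_size_error")
})

test_that("kernel regression with full enumeration matches exact Shapley", {
  M <- 8
  bg <- std_background(M, B = 15, seed = 9)
  vf <- value_function_spec(bg)
  f <- interaction_model(M)
  set.seed(10)
  X <- matrix(rnorm(3 * M), 3, M)
  colnames(X) <- colnames(bg)
  am <- sampled_shapley(f, X, vf, n_coalitions = 2^M - 2)
  expect_equal(am$method, "exact")
  for (i in 1:3) {
    phi <- exact_shapley(f, X[i, ], vf)
    expect_lt(max(abs(am$values[i, ] - phi)), 1e-6)
  }
  # base value is the mean background prediction
  expect_equal(am$base_value, mean(predict_prob(f, bg)), tolerance = 1e-9)
})

test_that("sampled attribution recovers the additive closed form and is seeded", {
  M <- 10
  bg <- std_background(M, B = 20, seed = 12)
  vf <- value_function_spec(bg)
  w <- seq(-0.2, 0.25, length.out = M)
  g <- linear_prob_model(w, intercept = 0.4)
  set.seed(13)
  X <- matrix(rnorm(2 * M), 2, M)
  colnames(X) <- colnames(bg)
  am <- sampled_shapley(g, X, vf, n_coalitions = 200, seed = 99)
  closed <- t(apply(X, 1, function(x) w * (x - colMeans(bg))))
  expect_lt(max(abs(am$values - closed)), 0.02)
  am2 <- sampled_shapley(g, X, vf, n_coalitions = 200, seed = 99)
  expect_identical(am$values, am2$values)
  am3 <- sampled_shapley(g, X, vf, n_coalitions = 200, seed = 100)
  expect_false(identical(am$values, am3$values))
})

test_that("sampling error shrinks in expectation as coalitions grow (M = 8)", {
  M <- 8
  bg <- std_background(M, B = 10, seed = 14)
  vf <- value_function_spec(bg)
  f <- interaction_model(M)
  x <- c(0.9, -0.6, 1.4, 0.2, -1, 0.5, 0, 0.8)
  exact <- exact_shapley(f, x, vf)
  budgets <- c(2^M / 4, 2^M / 2, 2^M)
  mean_err <- vapply(budgets, function(nc) {
    errs <- vapply(1:6, function(s) {
      am <- sampled_shapley(f, matrix(x, 1, M,
                                      dimnames = list(NULL, colnames(bg))),
                            vf, n_coalitions = nc, seed = s)
      max(abs(am$values[1, ] - exact))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) <= 1e-12))
  expect_lt(mean_err[3], 1e-6)  # full enumeration is exact
})

test_that("global importance is the column mean of absolute attributions", {
  # single instance: |phi| itself
  a1 <- attribution_matrix(matrix(c(-0.3, 0.2, 0), 1, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))),
                           base_value = 0.5, method = "exact")
  expect_equal(global_importance(a1)$importance, c(0.3, 0.2, 0))
  # a zero column scores exactly zero importance
  m <- matrix(rnorm(12), 4, 3)
  m[, 2] <- 0
  colnames(m) <- c("x", "fbs", "z")
  imp <- global_importance(attribution_matrix(m, 0.4, "sampling"))
  expect_equal(imp$importance[2], 0)
  # random matrix matches a hand-computed mean of absolute values
  expect_equal(imp$importance, as.numeric(colMeans(abs(m))))
})
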