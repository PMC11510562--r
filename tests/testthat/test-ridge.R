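test_that("ridge_solve matches the normal-equations oracle and classical limits", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(20:60, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    alpha <- runif(1, 0.1, 5); beta <- runif(1, 0.1, 5)
    got <- ridge_solve(X, y, alpha, beta)
    want <- ridge_oracle(X, y, alpha, beta)
    expect_equal(got$m, want$m, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
  }

  # vanishing penalty recovers ordinary least squares
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5); y <- rnorm(20)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  got <- ridge_solve(X, y, 1e-12, 1)
  expect_equal(got$m, unname(ols[-1]), tolerance = 1e-8)
  expect_equal(got$b, unname(ols[1]), tolerance = 1e-8)

  # all-zero target gives the zero solution
  z <- ridge_solve(X, rep(0, 20), 1, 1)
  expect_equal(z$m, rep(0, 5))
  expect_equal(z$b, 0)

  expect_error(ridge_solve(X[1, , drop = FALSE], y[1], 1, 1), "degenerate")
  expect_error(ridge_solve(X, y, -1, 1), "positive")
})

test_that("fixed-hyperparameter fit equals classical ridge with lambda = alpha/beta", {
  set.seed(33)
  X <- matrix(rnorm(400), 40, 10)
  y <- X %*% rnorm(10) + rnorm(40, 0, 0.5)
  for (lambda in c(0.01, 1, 100)) {
    a <- ridge_solve(X, y, alpha = 3 * lambda, beta = 3)
    b <- ridge_solve(X, y, alpha = lambda, beta = 1)
    expect_equal(a$m, b$m, tolerance = 1e-10)
  }
})

test_that("evidence maximization recovers noiseless and noisy generators", {
  # noiseless: predictions reproduce the target almost exactly (the fit
  # terminates at numerically perfect interpolation)
  set.seed(7)
  X <- matrix(rnorm(600), 200, 3)
  y <- as.numeric(X %*% c(1, -0.5, 2)) + 0.3
  fit <- bayes_ridge(X, y)
  expect_true(fit$converged)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-3)

  # noisy: the noise precision estimate tracks the true noise sd
  set.seed(8)
  X <- matrix(rnorm(10000), 1000, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(1000, 0, 0.5)
  fit <- bayes_ridge(X, y)
  expect_gt(1 / sqrt(fit$beta), 0.4)
  expect_lt(1 / sqrt(fit$beta), 0.6)
})

test_that("doubling the target doubles weights and quarters the noise precision", {
  set.seed(12)
  X <- matrix(rnorm(300), 60, 5)
  y <- as.numeric(X %*% rnorm(5)) + rnorm(60, 0, 0.3)
  f1 <- bayes_ridge(X, y)
  f2 <- bayes_ridge(X, 2 * y)
  expect_equal(f2$coefficients, 2 * f1$coefficients, tolerance = 1e-6)
  expect_equal(f2$intercept, 2 * f1$intercept, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta / 4, tolerance = 1e-4)
})

test_that("log evidence is non-decreasing along the update path", {
  set.seed(9)
  for (rep in 1:5) {
    X <- matrix(rnorm(2000), 100, 20)
    y <- as.numeric(X %*% rnorm(20)) + rnorm(100, 0, runif(1, 0.2, 2))
    fit <- bayes_ridge(X, y)
    expect_true(all(diff(fit$log_evidence) > -1e-8))
  }
})

test_that("weight recovery improves with sample size", {
  # average weight error at n = 100 vs n = 1000, across seeds
  err <- function(n, seed) {
    set.seed(seed)
    w <- c(rnorm(10), rep(0, 10))
    X <- matrix(rbinom(n * 20, 1, 0.3), n, 20)
    y <- as.numeric(X %*% w) + rnorm(n, 0, 0.3)
    sqrt(mean((bayes_ridge(X, y)$coefficients - w)^2))
  }
  e_small <- mean(vapply(1:5, function(s) err(100, s), numeric(1)))
  e_large <- mean(vapply(1:5, function(s) err(1000, s + 100), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("degenerate targets are refused with an explicit error", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(bayes_ridge(X, rep(3, 20)), "constant")
  expect_error(soluprint:::.fit_metrics(rep(1, 5), rep(1, 5)), "constant")
})

test_that("prediction equals intercept plus on-bit coefficient sum", {
  ds <- make_fixture_dataset(n = 120, seed = 31)
  model <- fit_solubility(ds$table, molecules = ds$truth$molecules,
                          nbits = 1024)
  mol <- ds$truth$molecules[[7]]
  fp <- circular_fingerprint(mol, nbits = 1024)
  manual <- model$fit$intercept +
    sum(as_bit_vector(fp) * model$fit$coefficients)
  expect_equal(predict(model, fp), manual, tolerance = 1e-12)
  expect_equal(predict(model, ds$table$smiles[7]), manual, tolerance = 1e-12)

  # empty fingerprint predicts the intercept
  empty <- structure(list(nbits = 1024, on_bits = numeric(0),
                          bit_info = list(), radius = 2L),
                     class = "fingerprint")
  expect_equal(predict(model$fit, empty), model$fit$intercept)
  # mismatched width is refused
  wrong <- circular_fingerprint(mol, nbits = 512)
  expect_error(predict(model$fit, wrong), "match")
})

test_that("fit metrics follow their definitions on a hand-computed case", {
  met <- soluprint:::.fit_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(met$rmse, sqrt(1 / 3))
  expect_equal(met$r_squared, 0.5)

  # perfect predictions and mean predictions
  met <- soluprint:::.fit_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(met$rmse, 0)
  expect_equal(met$r_squared, 1)
  met <- soluprint:::.fit_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(met$r_squared, 0)
})

test_that("simulate and predictive intervals behave sensibly", {
  set.seed(20)
  X <- matrix(rnorm(600), 200, 3)
  y <- as.numeric(X %*% c(1, 2, -1)) + rnorm(200, 0, 0.4)
  fit <- bayes_ridge(X, y)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(200L, 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
  pr <- predict(fit, X[1:5, ], se.fit = TRUE)
  expect_true(all(pr$se.fit >= 1 / sqrt(fit$beta) - 1e-12))
})
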