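test_that("gls_solve reduces to OLS under identity covariance", {
  y <- c(1, 2, 3)
  X <- cbind("(Intercept)" = 1, x = c(0, 1, 2))
  sol <- gls_solve(y, X, diag(3))
  expect_equal(unname(sol$beta), c(1, 1), tolerance = 1e-12)
  expect_lt(sol$rss, 1e-24)

  # duplicate predictor column -> rank-deficiency error naming the column
  Xdup <- cbind(X, x_copy = X[, "x"])
  expect_error(gls_solve(y, Xdup, diag(3)), "x_copy")
})

test_that("whitened GLS agrees with the dense-inverse oracle", {
  withr::with_seed(21, {
    for (n in c(40, 200)) {
      tr <- simulate_yule_tree(n, seed = n)
      V <- vcv_from_tree(tr)
      X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rnorm(n))
      y <- drop(X %*% c(1, 2, -1)) +
        drop(crossprod(chol(V), rnorm(n))) * 0.5
      sol <- gls_solve(y, X, V)
      expect_equal(unname(sol$beta), gls_oracle(y, X, V), tolerance = 1e-8)
    }
  })
})

test_that("lambda profile matches independent evaluations and limits", {
  # star phylogeny: off-diagonals already zero -> profile flat in lambda
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1,G:1,H:1);")
  V <- vcv_from_tree(star)
  withr::with_seed(8, {
    y <- rnorm(8)
    X <- cbind("(Intercept)" = 1, x = rnorm(8))
  })
  lls <- vapply(seq(0, 1, 0.1), function(l) loglik_given_lambda(y, X, V, l),
                numeric(1))
  expect_lt(diff(range(lls)), 1e-8)

  # lambda = 0: equals the independent-Gaussian likelihood with per-tip
  # variances from diag(V), computed by the generic dense MVN formula
  tr <- simulate_yule_tree(30, seed = 31, unit_height = FALSE)
  V <- vcv_from_tree(tr)
  withr::with_seed(32, {
    X <- cbind("(Intercept)" = 1, x = rnorm(30))
    y <- drop(X %*% c(0.5, 1)) + rnorm(30)
  })
  for (l in c(0, 0.4, 1)) {
    W <- lambda_transform(V, l)
    b <- gls_oracle(y, X, W)
    r <- y - drop(X %*% b)
    s2 <- drop(t(r) %*% solve(W) %*% r) / length(y)
    ll_dense <- -0.5 * (length(y) * log(2 * pi) +
                          determinant(s2 * W)$modulus[1] +
                          drop(t(r) %*% solve(s2 * W) %*% r))
    expect_equal(loglik_given_lambda(y, X, V, l), ll_dense,
                 tolerance = 1e-8)
  }

  # likelihood is invariant to a global rescaling of V (sigma2 compensates)
  expect_equal(loglik_given_lambda(y, X, 3.7 * V, 0.6),
               loglik_given_lambda(y, X, V, 0.6), tolerance = 1e-9)
})

test_that("ML lambda attains the 1001-point grid maximum", {
  tr <- simulate_yule_tree(100, seed = 77)
  d <- simulate_traits(tr, simulation_spec(
    lambda = 0.7, beta = c(x1 = 1, x2 = -0.5), sigma2 = 0.5, seed = 78))
  V <- vcv_from_tree(tr)
  X <- cbind("(Intercept)" = 1, x1 = d$x1, x2 = d$x2)
  y <- d$log_price
  fit <- fit_pgls(y, X, V)
  grid <- seq(0, 1, length.out = 1001)
  ll_grid <- vapply(grid, function(l) loglik_given_lambda(y, X, V, l),
                    numeric(1))
  expect_gte(fit$loglik, max(ll_grid) - 1e-6)
  # invariant: loglik at lambda-hat beats every coarse grid point too
  expect_gte(fit$loglik, max(fit$profile$loglik) - 1e-6)
})

test_that("fit_pgls matches nlme::gls with a Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(60, seed = 41)
  d <- simulate_traits(tr, simulation_spec(
    lambda = 0.6, beta = c(x1 = 1.2, x2 = -0.4), sigma2 = 0.4, seed = 42))
  fit <- pgls(log_price ~ x1 + x2, d, tr)
  dd <- as.data.frame(d)
  g <- nlme::gls(log_price ~ x1 + x2, data = dd,
                 correlation = ape::corPagel(0.5, tr, form = ~species_id),
                 method = "ML")
  expect_equal(fit$lambda, unname(coef(g$modelStruct$corStruct)),
               tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
})

test_that("lambda fixed at 0 on an ultrametric tree reduces to OLS", {
  tr <- simulate_yule_tree(50, seed = 51)
  withr::with_seed(52, {
    x <- rnorm(50)
    y <- 1 + 0.5 * x + rnorm(50)
  })
  d <- tibble::tibble(species_id = tr$tip.label, x = x, y = y)
  fit <- pgls(y ~ x, d, tr, lambda = 0)
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("lambda estimation recovers independence and Brownian limits", {
  lam0 <- lam1 <- numeric(50)
  for (i in 1:50) {
    tr <- simulate_yule_tree(100, seed = 1000 + i)
    d0 <- simulate_traits(tr, simulation_spec(
      lambda = 0, beta = c(x1 = 1), sigma2 = 0.5, seed = 2000 + i))
    d1 <- simulate_traits(tr, simulation_spec(
      lambda = 1, beta = c(x1 = 1), sigma2 = 0.5, seed = 3000 + i))
    lam0[i] <- pgls(log_price ~ x1, d0, tr)$lambda
    lam1[i] <- pgls(log_price ~ x1, d1, tr)$lambda
  }
  expect_lt(median(lam0), 0.1)
  expect_gt(median(lam1), 0.9)
})

test_that("a perfect linear fit gives vanishing residual variance and r2 = 1", {
  tr <- simulate_yule_tree(20, seed = 61)
  withr::with_seed(62, x <- rnorm(20))
  d <- tibble::tibble(species_id = tr$tip.label, x = x, y = 2 + 3 * x)
  fit <- pgls(y ~ x, d, tr)
  expect_lt(fit$sigma2, 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$beta), c(2, 3), tolerance = 1e-8)
})

test_that("AICc follows the closed form and tends to AIC", {
  expect_equal(aicc(-100, K = 3, n = 217), 206 + 24 / 213, tolerance = 1e-12)
  expect_equal(aicc(-100, K = 3, n = 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, K = 3, n = 4), "n > K")

  # two-model delta matches hand computation
  a1 <- aicc(-50, K = 4, n = 100)   # 108 + 40/95
  a2 <- aicc(-52, K = 3, n = 100)   # 110 + 24/96
  expect_equal(a1, 108 + 40 / 95, tolerance = 1e-12)
  expect_equal(a2 - a1, (110 + 0.25) - (108 + 40 / 95), tolerance = 1e-12)
})

test_that("pgls front end handles complete cases, alignment and accessors", {
  tr <- simulate_yule_tree(30, seed = 71)
  d <- simulate_traits(tr, simulation_spec(
    lambda = 0.5, beta = c(x1 = 1), sigma2 = 0.3, seed = 72))
  d$x1[3] <- NA
  fit <- pgls(log_price ~ x1, d, tr)
  expect_equal(fit$n, 29)
  expect_equal(unname(fit$dropped["incomplete"]), 1)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(gl$nobs, 29)
  expect_lte(gl$adj.r.squared, gl$r.squared)
  expect_s3_class(autoplot(fit), "ggplot")
  rep <- pgls_report(fit)
  expect_equal(nrow(rep), 2)

  # shuffled row order must not change the fit (rows realign to the tree)
  fit2 <- pgls(log_price ~ x1, d[sample(nrow(d)), ], tr)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
})

test_that("t-interval coverage for beta is near nominal under the model", {
  # 90% intervals across replicated datasets should cover the truth for
  # close to 90% of replicates if the standard errors are calibrated
  n_rep <- 60
  covered <- matrix(NA, n_rep, 2)
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule_tree(80, seed = 5000 + i)
    d <- simulate_traits(tr, simulation_spec(
      lambda = 0.8, beta = c(x1 = 1, x2 = -0.5), sigma2 = 0.5,
      seed = 6000 + i))
    fit <- pgls(log_price ~ x1 + x2, d, tr)
    tcrit <- stats::qt(0.95, fit$df_residual)
    lo <- fit$beta - tcrit * fit$se
    hi <- fit$beta + tcrit * fit$se
    covered[i, ] <- c(lo["x1"] <= 1 & hi["x1"] >= 1,
                      lo["x2"] <= -0.5 & hi["x2"] >= -0.5)
  }
  rate <- mean(covered)   # pooled over both coefficients: 120 intervals
  expect_gte(rate, 0.85)
  expect_lte(rate, 0.98)
})
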