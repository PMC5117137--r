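test_that("complete-case MLE matches an explicit normal-equations solve", {
  # fixed 6-row worked fixture
  df <- data.frame(x = c(1.2, -0.4, 2.5, 0.7, -1.1, 1.9),
                   y = c(3.1, 0.2, 6.0, 1.9, -1.5, 4.4),
                   z = c(0.5, 0.1, -0.2, 0.9, 0.4, -0.6))
  df$y[0] <- NA  # fully observed variant first
  id <- as_incomplete(df, "y")
  th <- fit_imputation_mle(id, c("const", "x", "z"))
  X <- cbind(1, df$x, df$z)
  mu_oracle <- solve(t(X) %*% X, t(X) %*% df$y)
  expect_equal(th$mu, as.numeric(mu_oracle), tolerance = 1e-12)
  rss <- sum((df$y - X %*% mu_oracle)^2)
  expect_equal(th$sigma, rss / 6, tolerance = 1e-12)

  # with missingness the fit uses complete rows and the ML divisor n - t
  df2 <- df; df2$y[c(2, 5)] <- NA
  id2 <- as_incomplete(df2, "y")
  th2 <- fit_imputation_mle(id2, c("const", "x", "z"))
  keep <- c(1, 3, 4, 6)
  X2 <- X[keep, ]
  mu2 <- solve(t(X2) %*% X2, t(X2) %*% df$y[keep])
  expect_equal(th2$mu, as.numeric(mu2), tolerance = 1e-12)
  expect_equal(th2$sigma, sum((df$y[keep] - X2 %*% mu2)^2) / 4,
               tolerance = 1e-12)
})

test_that("noiseless data give the exact coefficients and a flagged zero variance", {
  df <- data.frame(x = 1:8, y = 2 + 3 * (1:8))
  id <- as_incomplete(df, "y")
  expect_warning(th <- fit_imputation_mle(id, c("const", "x")), "degenerate")
  expect_equal(th$mu, c(2, 3), tolerance = 1e-10)
  expect_lt(th$sigma, 1e-20)
})

test_that("posterior sigma draws match the inverse-chi-squared mean", {
  set.seed(11)
  fx <- make_fixture("nonnormal", n = 80, p_obs = 0.6, m = 2)
  fit <- fit_imputation_mle(fx$idata, fx$cfg$imputation_covariates)
  nd <- 1e4
  draws <- replicate(nd, draw_posterior_theta(fx$idata,
                     fx$cfg$imputation_covariates, fit = fit)$sigma)
  df <- fit$n_complete - length(fit$mu)
  expect_equal(mean(draws), fit$rss / (df - 2),
               tolerance = 4 * sd(draws) / sqrt(nd) / (fit$rss / (df - 2)))
  # reproducibility
  set.seed(5); a <- draw_posterior_theta(fx$idata, fx$cfg$imputation_covariates)
  set.seed(5); b <- draw_posterior_theta(fx$idata, fx$cfg$imputation_covariates)
  expect_identical(a, b)
})

test_that("imputed stacks preserve observed cells and honour the mode contract", {
  set.seed(22)
  fx <- make_fixture("subgroup", n = 100, p_obs = 0.5, m = 5,
                     mode = "frequentist")
  st <- fx$stack
  obs <- st$r == 1
  for (k in 1:5) {
    ck <- completed_data(st, k)
    expect_identical(ck$weight[obs], fx$idata$data$weight[obs])
    expect_false(anyNA(ck))
  }
  # frequentist: same theta for every k
  expect_true(all(vapply(st$theta_draws, function(t) {
    identical(t$mu, st$theta_hat$mu) && identical(t$sigma, st$theta_hat$sigma)
  }, logical(1))))
  # imputed values for the same subject still differ across k (residual draw)
  expect_gt(min(apply(st$imputed, 1, function(z) diff(range(z)))), 0)

  # bayesian: theta varies across k and between-variance is positive
  set.seed(23)
  stb <- impute(fx$idata, fx$cfg$imputation_covariates, m = 5,
                mode = "bayesian")
  sigmas <- vapply(stb$theta_draws, `[[`, numeric(1), "sigma")
  expect_gt(var(sigmas), 0)
  expect_error(impute(fx$idata, fx$cfg$imputation_covariates, m = 1,
                      mode = "bayesian"), "m >= 2")
})

test_that("a stack with nothing to impute is m identical copies", {
  set.seed(33)
  cfg <- scenario_config("nonnormal", n = 40, p_obs = 0.5)
  d <- generate_complete(cfg)
  id <- as_incomplete(d, "weight")
  expect_equal(id$t, 0)
  st <- impute(id, cfg$imputation_covariates, m = 3, mode = "frequentist")
  expect_identical(completed_data(st, 1), completed_data(st, 3))
  expect_identical(completed_data(st, 2)$weight, d$weight)
  big <- stacked_data(st)
  expect_equal(nrow(big), 120)
  expect_equal(attr(big, "subject"), rep(1:40, 3))
})

test_that("analysis fit returns OLS with model and HC1 sandwich covariances", {
  set.seed(44)
  n <- 300
  d <- data.frame(sex = rbinom(n, 1, 0.5), x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n)
  fit <- fit_analysis(d, "y", c("const", "x"))
  lmfit <- lm(y ~ x, data = d)
  expect_equal(fit$beta, unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(fit$vcov_model, unname(vcov(lmfit)), tolerance = 1e-10)
  expect_equal(fit$nu_com, n - 2)
  # 3-point exact fit: zero residuals, zero variances
  d3 <- data.frame(x = c(0, 1, 2), y = c(1, 3, 5))
  f3 <- suppressWarnings(fit_analysis(d3, "y", c("const", "x")))
  expect_equal(max(abs(f3$residuals)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f3$vcov_model)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f3$vcov_sandwich)), 0, tolerance = 1e-12)
  # subgroup filtering
  fit_m <- fit_analysis(d, "y", c("const", "x"), subgroup = "men")
  expect_equal(fit_m$n_used, sum(d$sex == 0))
  expect_error(fit_analysis(d[d$sex == 2, ], "y", c("const", "x")), "few rows|empty")
})

test_that("sandwich and model variances agree under homoscedasticity, diverge under heteroscedasticity", {
  set.seed(55)
  cfg <- scenario_config("heteroscedastic", n = 1e5, p_obs = 0.4)
  d <- generate_complete(cfg)
  # weight model errors are heteroscedastic by sex
  fw <- fit_analysis(d, "weight", c("const", "sex", "age", "height"))
  rel <- abs(diag(fw$vcov_sandwich) - diag(fw$vcov_model)) /
    diag(fw$vcov_model)
  # sex coefficient variance differs beyond Monte Carlo error (~0.5% at this n)
  expect_gt(rel[2], 0.02)
  # homoscedastic null scenario: agreement within 5%
  cfg0 <- scenario_config("nonnormal", n = 1e5, p_obs = 0.4)
  d0 <- generate_complete(cfg0)
  f0 <- fit_analysis(d0, "weight", c("const", "age", "height"))
  rel0 <- abs(diag(f0$vcov_sandwich) - diag(f0$vcov_model)) /
    diag(f0$vcov_model)
  expect_lt(max(rel0), 0.05)
})

test_that("interaction terms in the covariate declaration are elementwise products", {
  d <- data.frame(weight = c(1, 2, 3), sex = c(0, 1, 1), y = c(1, 1, 1))
  X <- build_design(d, c("const", "weight", "weight:sex"))
  expect_equal(X[, "weight:sex"], c(0, 2, 3))
  expect_error(build_design(d, "nope"), "unknown covariate")
})
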