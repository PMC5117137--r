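test_that("stacked point estimate equals single-imputation OLS when m = 1 and complete-data OLS when t = 0", {
  set.seed(12)
  fx <- make_fixture("heteroscedastic", n = 80, p_obs = 0.5, m = 1)
  beta <- rw_point_estimate(fx$stack, "loginsindex",
                            fx$cfg$analysis_covariates)
  single <- fit_analysis(completed_data(fx$stack, 1), "loginsindex",
                         fx$cfg$analysis_covariates)
  expect_equal(beta, single$beta, tolerance = 1e-10)

  cfg <- scenario_config("heteroscedastic", n = 80, p_obs = 0.5)
  d <- generate_complete(cfg)
  id <- as_incomplete(d, "weight")
  st <- impute(id, cfg$imputation_covariates, m = 4, mode = "frequentist")
  beta0 <- rw_point_estimate(st, "loginsindex", cfg$analysis_covariates)
  full <- fit_analysis(d, "loginsindex", cfg$analysis_covariates)
  expect_equal(beta0, full$beta, tolerance = 1e-10)

  # bayesian stacks are rejected: the variance theory assumes fixed theta
  set.seed(13)
  stb <- impute(fx$idata, fx$cfg$imputation_covariates, m = 2,
                mode = "bayesian")
  expect_error(rw_point_estimate(stb, "loginsindex",
                                 fx$cfg$analysis_covariates), "frequentist")
})

test_that("point estimate solves the averaged estimating equation (Newton oracle)", {
  set.seed(14)
  fx <- make_fixture("heteroscedastic", n = 40, p_obs = 0.5, m = 2)
  cov <- fx$cfg$analysis_covariates
  beta <- rw_point_estimate(fx$stack, "loginsindex", cov)
  # independent Newton solve of sum_i m^-1 sum_k x_ik (y_i - x_ik b) = 0
  b <- rep(0, length(cov))
  for (it in 1:60) {
    G <- rep(0, length(cov)); J <- matrix(0, length(cov), length(cov))
    for (k in 1:2) {
      dk <- completed_data(fx$stack, k)
      X <- build_design(dk, cov)
      G <- G + colSums(X * (dk$loginsindex - as.numeric(X %*% b))) / 2
      J <- J - crossprod(X) / 2
    }
    b <- b - solve(J, G)
  }
  expect_equal(beta, as.numeric(b), tolerance = 1e-8)
  # the estimating equation is satisfied at the returned estimate
  expect_lt(max(abs(G)), 1e-6)
})

test_that("score bundle entries match finite-difference differentiation of the log-likelihood", {
  fx <- tiny_fixture(n = 8, seed = 15, m = 2)
  id <- fx$idata; st <- fx$stack
  bnd <- build_score_bundle(id, st)
  th <- c(st$theta_hat$mu, st$theta_hat$sigma)
  icov <- fx$imp_covariates
  obs <- id$r == 1
  # observed-value scores
  for (i in which(obs)) {
    x <- as.numeric(build_design(id$data[i, , drop = FALSE], icov))
    g <- fd_gradient(function(t) loglik_one(t, id$data$weight[i], x), th)
    expect_equal(bnd$s_obs[i, ], g, tolerance = 1e-6)
  }
  expect_true(all(bnd$s_obs[!obs, ] == 0))
  # imputed-value scores, each imputation
  n <- id$n
  for (k in 1:2) for (i in which(!obs)) {
    ck <- completed_data(st, k)
    x <- as.numeric(build_design(ck[i, , drop = FALSE], icov))
    g <- fd_gradient(function(t) loglik_one(t, ck$weight[i], x), th)
    expect_equal(bnd$S_mis[(k - 1) * n + i, ], g, tolerance = 1e-6)
  }
  expect_true(all(bnd$S_mis[rep(obs, 2), ] == 0))
  # averaged Hessian: sum of per-complete-row fd Hessians / n
  Hsum <- matrix(0, bnd$p, bnd$p)
  for (i in which(obs)) {
    x <- as.numeric(build_design(id$data[i, , drop = FALSE], icov))
    Hsum <- Hsum + fd_hessian(function(t) loglik_one(t, id$data$weight[i], x), th)
  }
  expect_equal(bnd$H_bar, Hsum / n, tolerance = 1e-4)
  # D rows: -Hbar^{-1} s_obs^T, zero for incomplete subjects
  for (i in which(obs))
    expect_equal(bnd$D[i, ],
                 as.numeric(-solve(bnd$H_bar) %*% bnd$s_obs[i, ]),
                 tolerance = 1e-10)
  expect_true(all(bnd$D[!obs, ] == 0))
})

test_that("complete-row scores sum to zero at the MLE", {
  set.seed(16)
  fx <- make_fixture("heteroscedastic", n = 60, p_obs = 0.5, m = 2)
  bnd <- build_score_bundle(fx$idata, fx$stack)
  expect_equal(max(abs(colSums(bnd$s_obs))), 0, tolerance = 1e-7)
})

test_that("Gamma equals the brute-force loop implementation on a tiny fixture", {
  fx <- tiny_fixture(n = 6, seed = 17, m = 2)
  cov <- fx$analysis_covariates
  beta <- rw_point_estimate(fx$stack, "loginsindex", cov)
  bnd <- build_score_bundle(fx$idata, fx$stack)
  comp <- rw_variance(bnd, fx$stack, beta, "loginsindex", cov)
  oracle <- rw_gamma_loops(fx$idata, fx$stack, "loginsindex", cov)
  expect_equal(beta, as.numeric(oracle$beta), tolerance = 1e-10)
  expect_equal(unname(comp$Gamma), unname(oracle$Gamma), tolerance = 1e-10)

  # and with a subgroup analysis on a slightly larger fixture
  set.seed(18)
  fx2 <- make_fixture("subgroup", n = 30, p_obs = 0.4, m = 2, seed = 18)
  cov2 <- fx2$cfg$analysis_covariates
  beta2 <- rw_point_estimate(fx2$stack, "loginsindex", cov2, "men")
  bnd2 <- build_score_bundle(fx2$idata, fx2$stack)
  comp2 <- rw_variance(bnd2, fx2$stack, beta2, "loginsindex", cov2, "men")
  oracle2 <- rw_gamma_loops(fx2$idata, fx2$stack, "loginsindex", cov2, "men")
  expect_equal(unname(comp2$Gamma), unname(oracle2$Gamma), tolerance = 1e-10)
})

test_that("with no missing data Gamma reduces to the HC0 sandwich covariance", {
  set.seed(19)
  cfg <- scenario_config("heteroscedastic", n = 120, p_obs = 0.5)
  d <- generate_complete(cfg)
  id <- as_incomplete(d, "weight")
  st <- impute(id, cfg$imputation_covariates, m = 3, mode = "frequentist")
  beta <- rw_point_estimate(st, "loginsindex", cfg$analysis_covariates)
  bnd <- build_score_bundle(id, st)
  comp <- rw_variance(bnd, st, beta, "loginsindex", cfg$analysis_covariates)
  expect_equal(max(abs(comp$kappa)), 0)
  X <- build_design(d, cfg$analysis_covariates)
  lmfit <- lm(d$loginsindex ~ X - 1)
  hc0 <- unname(sandwich::vcovHC(lmfit, type = "HC0"))
  expect_equal(unname(comp$Gamma), hc0, tolerance = 1e-10)
})

test_that("structural invariants: PSD pieces, symmetry, permutation invariance", {
  set.seed(21)
  for (rep in 1:5) {
    fx <- make_fixture("heteroscedastic", n = 40, p_obs = 0.5, m = 3,
                       seed = 100 + rep)
    cov <- fx$cfg$analysis_covariates
    beta <- rw_point_estimate(fx$stack, "loginsindex", cov)
    bnd <- build_score_bundle(fx$idata, fx$stack)
    comp <- rw_variance(bnd, fx$stack, beta, "loginsindex", cov)
    expect_true(all(eigen(comp$Lambda, only.values = TRUE)$values > -1e-10))
    expect_true(all(eigen(comp$Omega, only.values = TRUE)$values > -1e-10))
    expect_equal(comp$tau, t(comp$tau), tolerance = 1e-12)
    expect_equal(comp$Gamma, t(comp$Gamma), tolerance = 1e-12)
  }
  # permuting subject order leaves Gamma unchanged
  set.seed(31)
  fx <- make_fixture("heteroscedastic", n = 50, p_obs = 0.5, m = 2, seed = 31)
  cov <- fx$cfg$analysis_covariates
  g1 <- local({
    beta <- rw_point_estimate(fx$stack, "loginsindex", cov)
    bnd <- build_score_bundle(fx$idata, fx$stack)
    rw_variance(bnd, fx$stack, beta, "loginsindex", cov)$Gamma
  })
  perm <- sample(fx$idata$n)
  id_p <- as_incomplete(fx$idata$data[perm, ], "weight")
  st_p <- fx$stack
  st_p$data <- fx$stack$data[perm, ]
  st_p$r <- fx$stack$r[perm]
  inv <- order(perm)
  st_p$miss_idx <- sort(inv[fx$stack$miss_idx])
  st_p$imputed <- fx$stack$imputed[order(inv[fx$stack$miss_idx]), , drop = FALSE]
  g2 <- local({
    beta <- rw_point_estimate(st_p, "loginsindex", cov)
    bnd <- build_score_bundle(id_p, st_p)
    rw_variance(bnd, st_p, beta, "loginsindex", cov)$Gamma
  })
  expect_equal(unname(g1), unname(g2), tolerance = 1e-9)
})

test_that("Wald intervals use normal quantiles and flag negative variances", {
  comp <- list(Gamma = diag(c(1, 0)))
  ci <- rw_interval(c(0, 3), comp, 0.95)
  expect_equal(unname(ci[1, ]), c(-1, 1) * qnorm(0.975), tolerance = 1e-9)
  expect_equal(unname(ci[2, ]), c(3, 3))
  comp_bad <- list(Gamma = diag(c(1, -0.1)))
  expect_error(rw_interval(c(0, 0), comp_bad, 0.95), "2")
})

test_that("variance estimates from m and 2m imputations agree within Monte Carlo noise", {
  set.seed(41)
  cfg <- scenario_config("subgroup", n = 400, p_obs = 0.5)
  id <- apply_mdm(generate_complete(cfg), cfg, on_degenerate = "resample")
  v <- sapply(c(2, 10, 50), function(m) {
    set.seed(1000 + m)
    fit <- rw_mi(id, cfg$imputation_covariates, "loginsindex",
                 cfg$analysis_covariates, "men", m = m)
    fit$var[3]
  })
  expect_lt(abs(v[2] - v[3]) / v[3], 0.25)
  expect_lt(abs(v[1] - v[3]) / v[3], 0.6)
})

test_that("score-bundle CSV hand-off round-trips S_mis and D", {
  set.seed(51)
  fx <- make_fixture("heteroscedastic", n = 20, p_obs = 0.5, m = 2, seed = 51)
  bnd <- build_score_bundle(fx$idata, fx$stack)
  dir <- tempfile(); dir.create(dir)
  write_score_bundle(bnd, dir)
  back <- read_score_bundle(dir, p = bnd$p)
  expect_equal(back$S_mis, bnd$S_mis, tolerance = 1e-12)
  expect_equal(back$D, bnd$D, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
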