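# Independent oracles used across the suite.  These deliberately avoid the
# package's vectorized code paths: explicit normal equations, central
# finite differences, and naive nested loops.

# log-likelihood of one imputation-model observation; sigma is a VARIANCE
loglik_one <- function(theta, y, x) {
  mu <- theta[-length(theta)]
  sig <- theta[length(theta)]
  0.5 * (-log(2 * pi) - log(sig) - (y - sum(x * mu))^2 / sig)
}

fd_gradient <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, theta, h = 1e-4) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    tpp <- tpm <- tmp <- tmm <- theta
    tpp[a] <- tpp[a] + h; tpp[b] <- tpp[b] + h
    tpm[a] <- tpm[a] + h; tpm[b] <- tpm[b] - h
    tmp[a] <- tmp[a] - h; tmp[b] <- tmp[b] + h
    tmm[a] <- tmm[a] - h; tmm[b] <- tmm[b] - h
    H[a, b] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
  }
  H
}

# Naive loop implementation of the Robins-Wang variance, straight from the
# printed formulas, one subject and one imputation at a time.
rw_gamma_loops <- function(idata, stack, outcome, covariates,
                           subgroup = NULL) {
  theta <- stack$theta_hat
  n <- idata$n
  m <- stack$m
  icov <- theta$covariates
  p <- length(theta$mu) + 1
  q <- length(covariates)

  score_vec <- function(row_df, yval) {
    x <- as.numeric(build_design(row_df, icov))
    e <- yval - sum(x * theta$mu)
    c(x * e / theta$sigma,
      0.5 * (-1 / theta$sigma + e^2 / theta$sigma^2))
  }
  hess_mat <- function(row_df, yval) {
    x <- as.numeric(build_design(row_df, icov))
    e <- yval - sum(x * theta$mu)
    H <- matrix(0, p, p)
    H[1:(p - 1), 1:(p - 1)] <- -outer(x, x) / theta$sigma
    H[1:(p - 1), p] <- -x * e / theta$sigma^2
    H[p, 1:(p - 1)] <- H[1:(p - 1), p]
    H[p, p] <- 1 / (2 * theta$sigma^2) - e^2 / theta$sigma^3
    H
  }

  obs <- idata$r == 1
  yv <- idata$data[[idata$missing_col]]

  Hbar <- matrix(0, p, p)
  for (i in which(obs))
    Hbar <- Hbar + hess_mat(idata$data[i, , drop = FALSE], yv[i])
  Hbar <- Hbar / n
  Hinv <- solve(Hbar)

  D <- matrix(0, n, p)
  for (i in which(obs))
    D[i, ] <- as.numeric(-Hinv %*% score_vec(idata$data[i, , drop = FALSE], yv[i]))

  # point estimate: OLS on stacked subgroup rows (re-derived via normal eqs)
  XtX <- matrix(0, q, q); Xty <- numeric(q)
  for (k in seq_len(m)) {
    dk <- completed_data(stack, k)
    keep <- if (identical(subgroup, "men")) dk$sex == 0 else rep(TRUE, n)
    for (i in which(keep)) {
      x <- as.numeric(build_design(dk[i, , drop = FALSE], covariates))
      XtX <- XtX + outer(x, x)
      Xty <- Xty + x * dk[[outcome]][i]
    }
  }
  beta <- solve(XtX, Xty)

  u_arr <- array(0, c(n, m, q))
  s_mis <- array(0, c(n, m, p))
  tau <- matrix(0, q, q)
  for (k in seq_len(m)) {
    dk <- completed_data(stack, k)
    keep <- if (identical(subgroup, "men")) dk$sex == 0 else rep(TRUE, n)
    for (i in seq_len(n)) {
      x <- as.numeric(build_design(dk[i, , drop = FALSE], covariates))
      if (keep[i]) {
        u_arr[i, k, ] <- x * (dk[[outcome]][i] - sum(x * beta))
        tau <- tau + outer(x, x)
      }
      if (!obs[i])
        s_mis[i, k, ] <- score_vec(dk[i, , drop = FALSE],
                                   dk[[idata$missing_col]][i])
    }
  }
  tau <- tau / (n * m)

  kappa <- matrix(0, q, p)
  for (i in seq_len(n)) for (k in seq_len(m))
    kappa <- kappa + outer(u_arr[i, k, ], s_mis[i, k, ])
  kappa <- kappa / (n * m)

  Lambda <- matrix(0, p, p)
  for (i in seq_len(n)) Lambda <- Lambda + outer(D[i, ], D[i, ])
  Lambda <- Lambda / n

  ubar <- matrix(0, n, q)
  for (i in seq_len(n)) for (k in seq_len(m))
    ubar[i, ] <- ubar[i, ] + u_arr[i, k, ] / m

  Omega <- matrix(0, q, q)
  for (i in seq_len(n)) Omega <- Omega + outer(ubar[i, ], ubar[i, ])
  Omega <- Omega / n

  cross <- matrix(0, q, q)
  for (i in seq_len(n)) {
    tmp <- kappa %*% outer(D[i, ], ubar[i, ])   # kappa d_i^T ubar_i
    cross <- cross + tmp + t(tmp)
  }
  cross <- cross / n

  Delta <- Omega + kappa %*% Lambda %*% t(kappa) + cross
  ti <- solve(tau)
  list(beta = beta, Gamma = ti %*% Delta %*% t(ti) / n)
}

# minimal fixture: imputation model weight ~ height (p = 2), analysis
# model loginsindex ~ const + weight (q = 2)
tiny_fixture <- function(n = 8, seed = 1, m = 2, n_mis = 2) {
  set.seed(seed)
  d <- data.frame(sex = rbinom(n, 1, 0.5), height = 1.7 + 0.1 * rnorm(n))
  d$weight <- 40 * d$height + 5 * rnorm(n)
  d$loginsindex <- 1.8 + 0.011 * d$weight + 0.5 * rnorm(n)
  d$weight[sample.int(n, n_mis)] <- NA
  idata <- as_incomplete(d, "weight")
  stack <- impute(idata, "height", m = m, mode = "frequentist")
  list(idata = idata, stack = stack,
       imp_covariates = "height",
       analysis_covariates = c("const", "weight"),
       outcome = "loginsindex")
}

# small reproducible incomplete dataset from a preset; n below the
# config floor is handled by generating more rows and slicing
make_fixture <- function(name = "heteroscedastic", n = 60, p_obs = 0.5,
                         seed = 42, m = 2, mode = "frequentist") {
  set.seed(seed)
  cfg <- scenario_config(name, n = max(n, 20), p_obs = p_obs)
  d <- generate_complete(cfg)[seq_len(n), , drop = FALSE]
  idata <- apply_mdm(d, cfg, on_degenerate = "resample")
  stack <- impute(idata, cfg$imputation_covariates, m = m, mode = mode)
  list(cfg = cfg, idata = idata, stack = stack)
}
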