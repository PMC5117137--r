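# Full mechanism bootstrapping: single frequentist imputation for the
# point estimate, then T bootstrap replications that resample rows of the
# singly imputed dataset, re-impose missingness (observed pattern or a
# fitted missingness model), re-impute and refit the analysis.

#' FMB point estimate: single imputation plus analysis fit
#'
#' Imputes the incomplete dataset once with parameters fixed at the
#' complete-case MLE (the same frequentist engine as Robins-Wang) and
#' applies the analysis procedure to the completed data.
#'
#' @inheritParams rubin_mi
#' @return list: \code{beta}, \code{fit} (the \code{analysis_fit}),
#'   \code{imputed} (the singly imputed data.frame), \code{data} (input),
#'   plus the model declarations, class \code{fmb_estimate}.
#' @export
fmb_estimate <- function(data, imp_covariates, outcome, analysis_covariates,
                         subgroup = NULL) {
  stack <- impute(data, imp_covariates, m = 1, mode = "frequentist")
  completed <- completed_data(stack, 1)
  fit <- fit_analysis(completed, outcome, analysis_covariates, subgroup)
  out <- list(beta = fit$beta, fit = fit, imputed = completed, data = data,
              imp_covariates = imp_covariates, outcome = outcome,
              analysis_covariates = analysis_covariates, subgroup = subgroup)
  class(out) <- "fmb_estimate"
  out
}

# Refit imputation model and singly impute, lean path for the bootstrap
# inner loop.  Returns the completed outcome-column values, or NULL when
# the imputation model cannot be fitted (too few complete rows).
.quick_impute <- function(df, r, missing_col, covariates) {
  obs <- r == 1L
  n_c <- sum(obs)
  pm1 <- length(covariates)
  if (n_c <= pm1) return(NULL)
  X <- build_design(df, covariates)
  y <- df[[missing_col]]
  f <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  if (f$rank < pm1) return(NULL)
  sigma <- sum(f$residuals^2) / n_c
  mis <- which(!obs)
  y[mis] <- as.numeric(X[mis, , drop = FALSE] %*% f$coefficients) +
    sqrt(sigma) * stats::rnorm(length(mis))
  y
}

#' FMB bootstrap replications
#'
#' Each replicate resamples n rows with replacement from the singly
#' imputed dataset, sets values of the incomplete column to missing
#' (either positionally re-applying the observed missing data pattern, or
#' by Bernoulli draws from a missingness model fitted to the original
#' incomplete data), re-imputes once under the same imputation model
#' (refitted on the bootstrap complete cases), refits the analysis and
#' stores the coefficients.
#'
#' @param est an \code{\link{fmb_estimate}} result.
#' @param mdm_mode \code{"observed_mdp"} (re-apply the realized pattern;
#'   valid under MCAR) or \code{"modelled"} (simulate missingness from a
#'   fitted model; needed under MAR).
#' @param mdm_formula right-hand-side formula for the modelled mechanism;
#'   default regresses the observation indicator on all fully observed
#'   columns (logistic regression fitted once on the original data).
#' @param T number of bootstrap replications (>= 2).
#' @param positional_mdp if \code{FALSE}, the missingness indicator is
#'   resampled along with its row instead of being re-applied by
#'   position.  Default \code{TRUE} (re-apply by position).
#' @param max_failures abort if more than this fraction of replicates
#'   cannot be fitted (default 0.05); failed replicates are redrawn up to
#'   ten times each.
#' @return object of class \code{fmb_boot}: \code{replicates} (T x q),
#'   \code{beta_I}, \code{T}, \code{failures}, and what
#'   \code{\link{bootstrap_interval}} needs for BCa.
#' @export
fmb_bootstrap <- function(est, mdm_mode = c("observed_mdp", "modelled"),
                          mdm_formula = NULL, T = 2500,
                          positional_mdp = TRUE, max_failures = 0.05) {
  mdm_mode <- match.arg(mdm_mode)
  stopifnot(inherits(est, "fmb_estimate"), T >= 2)
  data <- est$data
  n <- data$n
  yI <- est$imputed
  q <- length(est$analysis_covariates)
  rows_sub <- .subgroup_rows
  mdm_fit <- NULL
  if (mdm_mode == "modelled") {
    if (is.null(mdm_formula)) {
      preds <- setdiff(names(data$data), data$missing_col)
      mdm_formula <- stats::reformulate(preds)
    }
    dd <- data$data
    dd$.robs <- data$r
    mdm_fit <- stats::glm(stats::update(mdm_formula, .robs ~ .),
                          family = stats::binomial(), data = dd)
  }
  reps <- matrix(NA_real_, T, q)
  failures <- 0L
  for (b in seq_len(T)) {
    ok <- FALSE
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- yI[idx, , drop = FALSE]
      r_boot <- if (mdm_mode == "observed_mdp") {
        if (positional_mdp) data$r else data$r[idx]
      } else {
        p_obs <- stats::predict(mdm_fit, newdata = boot, type = "response")
        stats::rbinom(n, 1, p_obs)
      }
      if (all(r_boot == 0L)) next
      ystar <- .quick_impute(boot, r_boot, data$missing_col,
                             est$imp_covariates)
      if (is.null(ystar)) next
      boot[[data$missing_col]] <- ystar
      keep <- rows_sub(boot, est$subgroup)
      if (sum(keep) <= q) next
      X <- build_design(boot[keep, , drop = FALSE], est$analysis_covariates)
      beta <- tryCatch(.ols_beta(X, boot[[est$outcome]][keep]),
                       error = function(e) NULL)
      if (is.null(beta)) next
      reps[b, ] <- beta
      ok <- TRUE
      break
    }
    if (!ok) failures <- failures + 1L
  }
  if (failures > max_failures * T)
    stop("FMB bootstrap: ", failures, " of ", T, " replicates failed")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  out <- list(replicates = reps, beta_I = est$beta, T = nrow(reps),
              failures = failures, mdm_mode = mdm_mode, estimate = est)
  class(out) <- "fmb_boot"
  out
}

#' Bootstrap variance of the FMB replicates
#'
#' @param reps an \code{\link{fmb_bootstrap}} result.
#' @return q-vector of sample variances (divisor T-1).
#' @export
bootstrap_variance <- function(reps) {
  stopifnot(inherits(reps, "fmb_boot"), reps$T >= 2)
  apply(reps$replicates, 2, stats::var)
}

#' Bootstrap confidence intervals for FMB
#'
#' Four flavours: \code{normal} (\eqn{\hat\beta \pm z\,SD^*});
#' \code{percentile} (empirical quantiles of the replicates);
#' \code{bc} (percentile corrected for median bias,
#' \eqn{z_0 = \Phi^{-1}(\#\{\hat\beta^* < \hat\beta\}/T)}, acceleration 0);
#' \code{bca_approx} (additionally an acceleration constant from a
#' jackknife over rows of the singly imputed dataset — an approximation,
#' since no exact acceleration formula exists for the full-mechanism
#' resampling scheme).
#'
#' @param reps an \code{\link{fmb_bootstrap}} result.
#' @param type interval flavour.
#' @param level confidence level.
#' @return q x 2 matrix of interval endpoints.
#' @export
bootstrap_interval <- function(reps, type = c("percentile", "normal", "bc",
                                              "bca_approx"),
                               level = 0.95) {
  type <- match.arg(type)
  stopifnot(inherits(reps, "fmb_boot"), level > 0, level < 1)
  R <- reps$replicates
  beta <- reps$beta_I
  q <- ncol(R)
  alpha <- (1 - level) / 2
  if (type == "normal") {
    halfw <- stats::qnorm(1 - alpha) * sqrt(bootstrap_variance(reps))
    return(cbind(lower = beta - halfw, upper = beta + halfw))
  }
  if (type == "percentile") {
    # type-1 (inverse ECDF) quantiles: endpoints are order statistics
    qs <- apply(R, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE, type = 1)
    return(cbind(lower = unname(qs[1, ]), upper = unname(qs[2, ])))
  }
  # BC / approximate BCa
  a <- rep(0, q)
  if (type == "bca_approx") a <- .jackknife_acceleration(reps$estimate)
  out <- matrix(NA_real_, q, 2, dimnames = list(NULL, c("lower", "upper")))
  z_alpha <- stats::qnorm(c(alpha, 1 - alpha))
  for (j in seq_len(q)) {
    frac <- mean(R[, j] < beta[j])
    if (frac == 0 || frac == 1)
      stop("bias correction undefined: all bootstrap replicates on one ",
           "side of the estimate for coefficient ", j)
    z0 <- stats::qnorm(frac)
    adj <- stats::pnorm(z0 + (z0 + z_alpha) / (1 - a[j] * (z0 + z_alpha)))
    out[j, ] <- stats::quantile(R[, j], probs = adj, names = FALSE, type = 1)
  }
  out
}

# Acceleration from leave-one-row-out analysis estimates on the singly
# imputed dataset, via the closed-form case-deletion OLS update.
.jackknife_acceleration <- function(est) {
  keep <- .subgroup_rows(est$imputed, est$subgroup)
  d <- est$imputed[keep, , drop = FALSE]
  X <- build_design(d, est$analysis_covariates)
  y <- d[[est$outcome]]
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  e <- y - as.numeric(X %*% beta)
  XtX_inv <- chol2inv(qr.R(qx))
  h <- rowSums((X %*% XtX_inv) * X)
  # beta_(i) = beta - (X'X)^{-1} x_i e_i / (1 - h_i)
  deltas <- (X %*% XtX_inv) * (e / (1 - h))   # n x q, row i = beta - beta_(i)
  centred <- sweep(deltas, 2, colMeans(deltas))
  num <- colSums(centred^3)
  den <- 6 * colSums(centred^2)^1.5
  ifelse(den > 0, num / den, 0)
}

#' @export
print.fmb_boot <- function(x, ...) {
  cat("FMB bootstrap:", x$T, "replicates (", x$failures, "failures ),",
      "mdm:", x$mdm_mode, "\n")
  ci <- bootstrap_interval(x, "percentile")
  tab <- data.frame(estimate = x$beta_I, se = sqrt(bootstrap_variance(x)),
                    lower = ci[, 1], upper = ci[, 2])
  print(tab, row.names = FALSE)
  invisible(x)
}
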