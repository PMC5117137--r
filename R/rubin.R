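# Rubin's rules with the Barnard-Rubin small-sample degrees of freedom,
# in standard (model-based within-variance) and robust (HC1 sandwich
# within-variance) variants.  Pooling is applied separately per
# regression coefficient.

#' Pool per-imputation estimates by Rubin's rules
#'
#' For each coefficient j: pooled estimate is the mean over imputations;
#' within-variance Wbar is the mean of the per-imputation variance
#' estimates; between-variance B is the sample variance of the estimates
#' (divisor m-1); total variance V = Wbar + (m+1)/m * B.  Degrees of
#' freedom use the Barnard-Rubin adjustment with \code{nu_com}, the
#' complete-data residual degrees of freedom.
#'
#' @param betas m x q matrix of per-imputation coefficient estimates.
#' @param withins m x q matrix of per-imputation variance estimates.
#' @param nu_com complete-data residual degrees of freedom
#'   (analysis rows minus q).
#' @param level confidence level for the reported intervals.
#' @return object of class \code{mi_estimate} with per-coefficient fields
#'   \code{beta}, \code{Wbar}, \code{B}, \code{V}, \code{gamma},
#'   \code{nu_star}, \code{ci} (q x 2), plus \code{m}, \code{nu_com}.
#' @export
pool_rubin <- function(betas, withins, nu_com, level = 0.95) {
  betas <- as.matrix(betas)
  withins <- as.matrix(withins)
  m <- nrow(betas)
  if (m < 2) stop("Rubin pooling requires m >= 2 imputations")
  stopifnot(all(dim(betas) == dim(withins)), all(withins > 0), nu_com >= 1)
  beta <- colMeans(betas)
  Wbar <- colMeans(withins)
  B <- apply(betas, 2, stats::var)
  V <- Wbar + (m + 1) / m * B
  nu_star <- barnard_rubin_df(B, Wbar, m, nu_com)
  gamma <- (1 + 1 / m) * B / (Wbar + (1 + 1 / m) * B)
  out <- list(beta = beta, Wbar = Wbar, B = B, V = V, gamma = gamma,
              nu_star = nu_star, m = m, nu_com = nu_com, level = level)
  out$ci <- rubin_interval(out, level)
  class(out) <- "mi_estimate"
  out
}

#' Barnard-Rubin adjusted degrees of freedom
#'
#' Small-sample degrees of freedom for the pooled t-interval:
#' \deqn{\hat\gamma = (1+1/m)B / \{W + (1+1/m)B\}}
#' \deqn{\nu = (m-1)\{1 + m W / ((m+1) B)\}^2}
#' \deqn{\hat\nu_{obs} = (1-\hat\gamma)\,\nu_{com}(\nu_{com}+1)/(\nu_{com}+3)}
#' \deqn{\nu^* = (\nu^{-1} + \hat\nu_{obs}^{-1})^{-1}}
#' When B = 0 (no missing information) the \eqn{\nu = \infty} limit is
#' taken exactly and \eqn{\nu^* = \hat\nu_{obs}}.
#'
#' @param B between-imputation variance(s), >= 0 (vectorized).
#' @param Wbar mean within-imputation variance(s), > 0.
#' @param m number of imputations.
#' @param nu_com complete-data residual degrees of freedom (>= 1).
#' @return adjusted degrees of freedom, same length as \code{B}.
#' @export
barnard_rubin_df <- function(B, Wbar, m, nu_com) {
  stopifnot(all(B >= 0), all(Wbar > 0), m >= 2, nu_com >= 1)
  gamma <- (1 + 1 / m) * B / (Wbar + (1 + 1 / m) * B)
  nu_obs <- (1 - gamma) * ((nu_com + 1) / (nu_com + 3)) * nu_com
  nu <- ifelse(B > 0,
               (m - 1) * (1 + (m / (m + 1)) * Wbar / ifelse(B > 0, B, 1))^2,
               Inf)
  ifelse(is.finite(nu), 1 / (1 / nu + 1 / nu_obs), nu_obs)
}

#' Student-t confidence intervals for a pooled MI estimate
#'
#' @param est an \code{\link{pool_rubin}} result.
#' @param level confidence level in (0,1).
#' @return q x 2 matrix of lower/upper endpoints
#'   \eqn{\hat\beta_j \pm t_{\nu^*_j} \sqrt{V_j}}.
#' @export
rubin_interval <- function(est, level = 0.95) {
  stopifnot(level > 0, level < 1)
  halfw <- stats::qt((1 + level) / 2, est$nu_star) * sqrt(est$V)
  cbind(lower = est$beta - halfw, upper = est$beta + halfw)
}

#' @export
print.mi_estimate <- function(x, ...) {
  tab <- data.frame(estimate = x$beta, se = sqrt(x$V),
                    Wbar = x$Wbar, B = x$B, df = x$nu_star,
                    lower = x$ci[, 1], upper = x$ci[, 2])
  cat("Rubin's MI pooled estimates (m =", x$m, "):\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Rubin's multiple imputation inference, end to end
#'
#' Imputes the incomplete column m times from the Bayesian posterior
#' predictive distribution (independent Jeffreys prior), fits the analysis
#' model to each completed dataset, and pools by Rubin's rules.  Both the
#' standard variant (model-based within-variances) and the robust variant
#' (HC1 sandwich within-variances) are returned; the pooled point
#' estimates are identical between variants.
#'
#' @param data an \code{\link{as_incomplete}} object.
#' @param imp_covariates imputation-model terms.
#' @param outcome analysis-model response column.
#' @param analysis_covariates analysis-model terms.
#' @param subgroup analysis row filter (see \code{\link{fit_analysis}}).
#' @param m number of imputations.
#' @param level confidence level.
#' @return list of class \code{rubin_mi_fit} with \code{standard} and
#'   \code{robust} \code{mi_estimate}s and the underlying stack.
#' @export
rubin_mi <- function(data, imp_covariates, outcome, analysis_covariates,
                     subgroup = NULL, m = 50, level = 0.95) {
  stack <- impute(data, imp_covariates, m, mode = "bayesian")
  q <- length(analysis_covariates)
  betas <- matrix(NA_real_, m, q)
  w_model <- matrix(NA_real_, m, q)
  w_sand <- matrix(NA_real_, m, q)
  nu_com <- NA_integer_
  for (k in seq_len(m)) {
    fit <- fit_analysis(completed_data(stack, k), outcome,
                        analysis_covariates, subgroup)
    betas[k, ] <- fit$beta
    w_model[k, ] <- diag(fit$vcov_model)
    w_sand[k, ] <- diag(fit$vcov_sandwich)
    nu_com <- fit$nu_com
  }
  out <- list(standard = pool_rubin(betas, w_model, nu_com, level),
              robust = pool_rubin(betas, w_sand, nu_com, level),
              stack = stack, betas = betas,
              covariates = analysis_covariates)
  class(out) <- "rubin_mi_fit"
  out
}

#' @export
print.rubin_mi_fit <- function(x, ...) {
  print(x$standard)
  invisible(x)
}
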