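# Normal linear imputation engine and the analysis-model OLS fit.
# The imputation model regresses the incomplete column on declared
# covariates; sigma is parameterized as the error VARIANCE throughout.

#' Build a design matrix from a covariate declaration
#'
#' Covariates are named columns of the data; \code{"const"} denotes an
#' explicit intercept column of ones and \code{"a:b"} the elementwise
#' product of columns \code{a} and \code{b}.  No implicit intercepts are
#' ever added.
#'
#' @param data data.frame.
#' @param covariates character vector of terms.
#' @return numeric matrix with one column per term.
#' @export
build_design <- function(data, covariates) {
  cols <- lapply(covariates, function(term) {
    if (term == "const") return(rep(1, nrow(data)))
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      stopifnot(all(parts %in% names(data)))
      return(Reduce(`*`, data[parts]))
    }
    if (!term %in% names(data)) stop("unknown covariate: ", term)
    data[[term]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

.subgroup_rows <- function(data, subgroup) {
  if (is.null(subgroup) || identical(subgroup, "all")) return(rep(TRUE, nrow(data)))
  if (identical(subgroup, "men")) return(data$sex == 0)
  if (is.logical(subgroup)) {
    stopifnot(length(subgroup) == nrow(data))
    return(subgroup)
  }
  stop("subgroup must be NULL, 'all', 'men', or a logical row filter")
}

#' Complete-case maximum likelihood fit of the imputation model
#'
#' OLS of the incomplete column on the imputation covariates over the
#' complete rows, with the maximum-likelihood error-variance divisor
#' (number of complete rows).
#'
#' @param data an \code{\link{as_incomplete}} object.
#' @param covariates imputation-model terms (include \code{"const"}).
#' @return object of class \code{theta}: \code{mu} (coefficients),
#'   \code{sigma} (error variance), plus the complete-row fit artifacts.
#' @export
fit_imputation_mle <- function(data, covariates) {
  obs <- data$r == 1L
  n_c <- sum(obs)
  pm1 <- length(covariates)
  if (n_c <= pm1) stop("too few complete rows (", n_c, ") for ", pm1, " covariates")
  X <- build_design(data$data[obs, , drop = FALSE], covariates)
  y <- data$data[[data$missing_col]][obs]
  qx <- qr(X)
  if (qx$rank < pm1) stop("rank-deficient imputation design")
  mu <- qr.coef(qx, y)
  res <- y - X %*% mu
  rss <- sum(res^2)
  sigma <- rss / n_c
  if (sigma < .Machine$double.eps * max(1, stats::var(y)))
    warning("degenerate imputation fit: residual variance is (numerically) zero")
  out <- list(mu = as.numeric(mu), sigma = sigma, covariates = covariates,
              rss = rss, n_complete = n_c,
              XtX_inv = chol2inv(qr.R(qx)))
  class(out) <- "theta"
  out
}

#' Draw imputation-model parameters from the Jeffreys posterior
#'
#' Standard normal linear model posterior under the independent Jeffreys
#' prior: \code{sigma} drawn as RSS over a chi-squared with
#' (complete rows - covariates) degrees of freedom, then \code{mu} from a
#' multivariate normal centred at the OLS estimate with covariance
#' \code{sigma * (X'X)^{-1}}.
#'
#' @inheritParams fit_imputation_mle
#' @param fit optional precomputed \code{\link{fit_imputation_mle}} result.
#' @return a \code{theta} object (one posterior draw).
#' @export
draw_posterior_theta <- function(data, covariates, fit = NULL) {
  if (is.null(fit)) fit <- fit_imputation_mle(data, covariates)
  pm1 <- length(fit$mu)
  df <- fit$n_complete - pm1
  if (df <= 2)
    warning("posterior for sigma has <= 2 degrees of freedom; draws are heavy-tailed")
  sigma <- fit$rss / stats::rchisq(1, df)
  L <- chol(sigma * fit$XtX_inv)
  mu <- fit$mu + as.numeric(t(L) %*% stats::rnorm(pm1))
  out <- list(mu = mu, sigma = sigma, covariates = covariates)
  class(out) <- "theta"
  out
}

#' Multiply impute the incomplete column
#'
#' In \code{bayesian} mode each imputation k uses an independent posterior
#' parameter draw (Rubin-style); in \code{frequentist} mode every
#' imputation is drawn from the predictive distribution evaluated at the
#' complete-case maximum likelihood estimate, so all m sets share the same
#' parameter value (Robins-Wang / FMB style).
#'
#' @inheritParams fit_imputation_mle
#' @param m number of imputations (>= 1; Rubin pooling needs >= 2).
#' @param mode \code{"bayesian"} or \code{"frequentist"}.
#' @return object of class \code{imputed_stack}: the original data, the
#'   index of missing rows, a t x m matrix of imputed values, the mode and
#'   parameter provenance (\code{theta_hat} or \code{theta_draws}).
#' @export
impute <- function(data, covariates, m, mode = c("bayesian", "frequentist")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "incomplete_data"), m >= 1)
  if (mode == "bayesian" && m < 2)
    stop("bayesian (Rubin) imputation requires m >= 2 for pooling")
  if (data$missing_col %in% unlist(strsplit(covariates, ":", fixed = TRUE)))
    stop("imputation covariates must not involve the incomplete column")
  fit <- fit_imputation_mle(data, covariates)
  mis <- which(data$r == 0L)
  Xmis <- build_design(data$data[mis, , drop = FALSE], covariates)
  imp <- matrix(NA_real_, length(mis), m)
  theta_draws <- vector("list", m)
  for (k in seq_len(m)) {
    th <- if (mode == "bayesian") {
      draw_posterior_theta(data, covariates, fit = fit)
    } else fit
    theta_draws[[k]] <- th
    imp[, k] <- as.numeric(Xmis %*% th$mu) +
      sqrt(th$sigma) * stats::rnorm(length(mis))
  }
  out <- list(data = data$data, r = data$r, n = data$n, t = data$t,
              missing_col = data$missing_col, miss_idx = mis,
              imputed = imp, m = m, mode = mode,
              covariates = covariates,
              theta_hat = if (mode == "frequentist") fit else NULL,
              theta_draws = if (mode == "bayesian") theta_draws else NULL)
  class(out) <- "imputed_stack"
  out
}

#' Extract the kth completed dataset from an imputed stack
#' @param stack an \code{\link{impute}} result.
#' @param k imputation index in 1..m.
#' @return data.frame with the missing cells filled in.
#' @export
completed_data <- function(stack, k) {
  stopifnot(inherits(stack, "imputed_stack"), k >= 1, k <= stack$m)
  d <- stack$data
  d[[stack$missing_col]][stack$miss_idx] <- stack$imputed[, k]
  d
}

#' Stack the m completed datasets into one mn-row dataset
#'
#' @param stack an \code{\link{impute}} result.
#' @return data.frame of mn rows with attributes \code{subject} (original
#'   row index i) and \code{imp} (imputation index k) recording provenance.
#' @export
stacked_data <- function(stack) {
  pieces <- lapply(seq_len(stack$m), function(k) completed_data(stack, k))
  out <- do.call(rbind, pieces)
  attr(out, "subject") <- rep(seq_len(stack$n), stack$m)
  attr(out, "imp") <- rep(seq_len(stack$m), each = stack$n)
  out
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack:", x$m, x$mode, "imputations of '", x$missing_col,
      "' (", x$t, "of", x$n, "rows )\n")
  invisible(x)
}

#' Fit the analysis model by OLS with model-based and sandwich variances
#'
#' The analysis procedure is a normal linear regression of \code{outcome}
#' on the declared covariates (explicit \code{"const"} term).  Both the
#' classical model-based covariance and the HC1 heteroscedasticity-robust
#' sandwich covariance (via \code{sandwich::vcovHC}) are returned.
#'
#' @param data data.frame (a completed dataset, or any complete table).
#' @param outcome name of the response column.
#' @param covariates analysis-model terms.
#' @param subgroup \code{NULL}/\code{"all"}, \code{"men"} (rows with
#'   \code{sex == 0}) or a logical row filter.
#' @return object of class \code{analysis_fit}: \code{beta},
#'   \code{vcov_model}, \code{vcov_sandwich}, \code{residuals},
#'   \code{nu_com} (residual df), \code{n_used}.
#' @export
fit_analysis <- function(data, outcome, covariates, subgroup = NULL) {
  rows <- .subgroup_rows(data, subgroup)
  if (!any(rows)) stop("empty analysis subgroup")
  d <- data[rows, , drop = FALSE]
  X <- build_design(d, covariates)
  y <- d[[outcome]]
  q <- ncol(X)
  if (nrow(X) <= q) stop("too few rows (", nrow(X), ") for ", q, " coefficients")
  fit <- stats::lm(y ~ X - 1)
  if (fit$rank < q) stop("rank-deficient analysis design")
  beta <- unname(stats::coef(fit))
  vc_model <- unname(stats::vcov(fit))
  vc_sand <- unname(sandwich::vcovHC(fit, type = "HC1"))
  out <- list(beta = beta, vcov_model = vc_model, vcov_sandwich = vc_sand,
              residuals = unname(stats::residuals(fit)),
              nu_com = nrow(X) - q, n_used = nrow(X),
              covariates = covariates, outcome = outcome)
  class(out) <- "analysis_fit"
  out
}

#' @export
print.analysis_fit <- function(x, ...) {
  tab <- data.frame(coef = x$covariates, estimate = x$beta,
                    se_model = sqrt(diag(x$vcov_model)),
                    se_sandwich = sqrt(diag(x$vcov_sandwich)))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Lean beta-only OLS used in tight simulation loops.
.ols_beta <- function(X, y) {
  f <- stats::lm.fit(X, y)
  if (f$rank < ncol(X)) stop("rank-deficient design")
  unname(f$coefficients)
}
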