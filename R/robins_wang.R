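# Robins-Wang frequentist multiple imputation: point estimation on the
# stacked imputed datasets and a variance estimator assembled from the
# imputation-model score function (imputer side) and the analysis-model
# estimating functions (analyst side).
#
# Division of labour mirrors the intended workflow: build_score_bundle()
# needs only imputer-side knowledge (the incomplete data, the stack and
# theta-hat); rw_variance() consumes (D, S_mis) plus the analyst's stack,
# point estimate and estimating-function declaration.

#' Robins-Wang point estimate on the stacked imputations
#'
#' Applies the analysis OLS to the mn stacked rows of a frequentist
#' imputed stack, treating rows as independent; this solves the averaged
#' estimating equation \eqn{\sum_i m^{-1}\sum_k u_{ik}(\hat\theta,\beta)=0}
#' with \eqn{u_{ik} = x_{ik}^T(y_i - x_{ik}\beta)}.
#'
#' @param stack a frequentist-mode \code{\link{impute}} result.
#' @param outcome analysis response column.
#' @param covariates analysis-model terms.
#' @param subgroup analysis row filter (see \code{\link{fit_analysis}}).
#' @return q-vector of coefficients.
#' @export
rw_point_estimate <- function(stack, outcome, covariates, subgroup = NULL) {
  stopifnot(inherits(stack, "imputed_stack"))
  if (stack$mode != "frequentist")
    stop("Robins-Wang requires a frequentist stack (imputations drawn at theta-hat)")
  big <- stacked_data(stack)
  rows <- .subgroup_rows(big, subgroup)
  X <- build_design(big[rows, , drop = FALSE], covariates)
  .ols_beta(X, big[[outcome]][rows])
}

#' Imputer-side score bundle for the Robins-Wang variance
#'
#' Evaluates, at the complete-case MLE \code{theta_hat} (with sigma the
#' error variance), the imputation-model score for each subject:
#' \deqn{\partial\ell/\partial\mu = ((y - x\mu)/\sigma)\,x^T,\qquad
#'       \partial\ell/\partial\sigma = \tfrac12(-1/\sigma + (y-x\mu)^2/\sigma^2)}
#' \code{s_obs} holds scores at observed values (zero rows for incomplete
#' subjects); \code{S_mis} holds scores at each imputed value (zero rows
#' for complete subjects), stacked over the m imputations.  \code{H_bar}
#' is the average over all n subjects of the second-derivative matrix,
#' with incomplete subjects contributing zero (the divisor stays n, so
#' that \code{Lambda} below estimates the asymptotic covariance of the
#' complete-case MLE).  Row i of \code{D} is
#' \eqn{d_i^T = -\bar H^{-1} s_i^{obs\,T}} for complete subjects and zero
#' otherwise.
#'
#' @param data the \code{\link{as_incomplete}} object the stack came from.
#' @param stack the frequentist \code{\link{impute}} result.
#' @param theta theta at which scores are evaluated; defaults to the
#'   stack's \code{theta_hat}.
#' @return object of class \code{score_bundle}: \code{S_mis} (mn x p),
#'   \code{s_obs} (n x p), \code{H_bar} (p x p), \code{D} (n x p).
#' @export
build_score_bundle <- function(data, stack, theta = stack$theta_hat) {
  stopifnot(inherits(stack, "imputed_stack"), !is.null(theta))
  covariates <- theta$covariates
  Xall <- build_design(data$data, covariates)
  mu <- theta$mu
  sig <- theta$sigma
  n <- data$n
  pm1 <- length(mu)
  p <- pm1 + 1
  obs <- data$r == 1L
  pred <- as.numeric(Xall %*% mu)

  score_rows <- function(X, y, fitted) {
    e <- y - fitted
    cbind(X * (e / sig), 0.5 * (-1 / sig + e^2 / sig^2))
  }

  y_obs <- data$data[[data$missing_col]]
  s_obs <- matrix(0, n, p)
  s_obs[obs, ] <- score_rows(Xall[obs, , drop = FALSE], y_obs[obs], pred[obs])

  m <- stack$m
  S_mis <- matrix(0, n * m, p)
  mis <- stack$miss_idx
  if (length(mis) > 0) {
    Xm <- Xall[mis, , drop = FALSE]
    pm <- pred[mis]
    for (k in seq_len(m)) {
      S_mis[(k - 1) * n + mis, ] <-
        score_rows(Xm, stack$imputed[, k], pm)
    }
  }

  # average Hessian over complete rows (zero contribution otherwise)
  Xo <- Xall[obs, , drop = FALSE]
  eo <- y_obs[obs] - pred[obs]
  H <- matrix(0, p, p)
  H[seq_len(pm1), seq_len(pm1)] <- -crossprod(Xo) / sig
  hms <- -colSums(Xo * eo) / sig^2
  H[seq_len(pm1), p] <- hms
  H[p, seq_len(pm1)] <- hms
  H[p, p] <- sum(1 / (2 * sig^2) - eo^2 / sig^3)
  H_bar <- H / n

  Hi <- tryCatch(solve(H_bar), error = function(e)
    stop("singular averaged Hessian in score bundle"))
  D <- matrix(0, n, p)
  D[obs, ] <- -s_obs[obs, , drop = FALSE] %*% t(Hi)

  out <- list(S_mis = S_mis, s_obs = s_obs, H_bar = H_bar, D = D,
              n = n, m = m, p = p, theta = theta)
  class(out) <- "score_bundle"
  out
}

#' Robins-Wang variance estimator from the score bundle and the stack
#'
#' Implements the matrix formulae
#' \deqn{\tau = (nm)^{-1}\sum_{ik} x_{ik}^T x_{ik},\quad
#'       \kappa = (nm)^{-1}\sum_{ik} u_{ik} s^{mis,k\,T}_i}
#' \deqn{\Lambda = n^{-1}\sum_i d_i^T d_i,\quad
#'       \Omega = n^{-1}\sum_i \bar u_i^T \bar u_i}
#' \deqn{\Delta = \Omega + \kappa\Lambda\kappa^T +
#'       n^{-1}\sum_i\{\kappa d_i^T \bar u_i + (\kappa d_i^T \bar u_i)^T\},
#'       \quad \Gamma = n^{-1}\tau^{-1}\Delta\tau^{-T}}
#' Subjects outside the analysis subgroup contribute zero estimating
#' functions (and zero rows of U) but remain in every i-indexed average,
#' whose divisor is always n.  The diagonal of \eqn{\Gamma} estimates the
#' variances of the stacked-imputation coefficients.
#'
#' @param bundle a \code{\link{build_score_bundle}} result.
#' @param stack the frequentist \code{\link{impute}} result.
#' @param beta the \code{\link{rw_point_estimate}} at which the
#'   estimating functions are evaluated.
#' @param outcome,covariates,subgroup the analysis specification.
#' @return object of class \code{rw_components} with fields \code{U},
#'   \code{u_bar}, \code{tau}, \code{kappa}, \code{Lambda}, \code{Omega},
#'   \code{Delta}, \code{Gamma}.
#' @export
rw_variance <- function(bundle, stack, beta, outcome, covariates,
                        subgroup = NULL) {
  stopifnot(inherits(bundle, "score_bundle"))
  n <- stack$n
  m <- stack$m
  q <- length(covariates)
  big <- stacked_data(stack)
  rows <- .subgroup_rows(big, subgroup)
  Xs <- build_design(big, covariates)
  resid <- big[[outcome]] - as.numeric(Xs %*% beta)
  w <- as.numeric(rows)          # zero out non-subgroup estimating functions
  U <- Xs * (resid * w)          # mn x q
  tau <- crossprod(Xs * sqrt(w)) / (n * m)
  if (rcond(tau) < .Machine$double.eps * 10) stop("singular tau matrix")

  # per-subject mean estimating function over the m imputations
  u_bar <- matrix(0, n, q)
  for (k in seq_len(m)) u_bar <- u_bar + U[(k - 1) * n + seq_len(n), , drop = FALSE]
  u_bar <- u_bar / m

  kappa <- crossprod(U, bundle$S_mis) / (n * m)      # q x p
  Lambda <- crossprod(bundle$D) / n                  # p x p
  Omega <- crossprod(u_bar) / n                      # q x q
  M <- kappa %*% crossprod(bundle$D, u_bar) / n      # q x q
  Delta <- Omega + kappa %*% Lambda %*% t(kappa) + M + t(M)
  tau_inv <- solve(tau)
  Gamma <- tau_inv %*% Delta %*% t(tau_inv) / n
  Gamma <- (Gamma + t(Gamma)) / 2
  dimnames(Gamma) <- list(covariates, covariates)
  out <- list(U = U, u_bar = u_bar, tau = tau, kappa = kappa,
              Lambda = Lambda, Omega = Omega, Delta = Delta, Gamma = Gamma,
              n = n, m = m)
  class(out) <- "rw_components"
  out
}

#' Wald intervals for Robins-Wang estimates
#'
#' Normal-quantile intervals based on the asymptotic variance
#' \eqn{\Gamma_{jj}}.
#'
#' @param beta point estimates.
#' @param components an \code{\link{rw_variance}} result.
#' @param level confidence level.
#' @return q x 2 matrix of interval endpoints.
#' @export
rw_interval <- function(beta, components, level = 0.95) {
  v <- diag(components$Gamma)
  if (any(v < 0))
    stop("negative Robins-Wang variance estimate for coefficient(s) ",
         paste(which(v < 0), collapse = ", "))
  halfw <- stats::qnorm((1 + level) / 2) * sqrt(v)
  cbind(lower = beta - halfw, upper = beta + halfw)
}

#' Robins-Wang multiple imputation inference, end to end
#'
#' Frequentist imputation at the complete-case MLE, point estimation on
#' the stacked imputations, score-based variance and Wald intervals.
#'
#' @inheritParams rubin_mi
#' @return list of class \code{rw_fit}: \code{beta}, \code{var}
#'   (diagonal of Gamma), \code{ci}, \code{components}, \code{stack}.
#' @export
rw_mi <- function(data, imp_covariates, outcome, analysis_covariates,
                  subgroup = NULL, m = 50, level = 0.95) {
  stack <- impute(data, imp_covariates, m, mode = "frequentist")
  beta <- rw_point_estimate(stack, outcome, analysis_covariates, subgroup)
  bundle <- build_score_bundle(data, stack)
  comp <- rw_variance(bundle, stack, beta, outcome, analysis_covariates,
                      subgroup)
  out <- list(beta = beta, var = diag(comp$Gamma),
              ci = rw_interval(beta, comp, level),
              components = comp, stack = stack,
              covariates = analysis_covariates, level = level)
  class(out) <- "rw_fit"
  out
}

#' @export
print.rw_fit <- function(x, ...) {
  tab <- data.frame(coef = x$covariates, estimate = x$beta,
                    se = sqrt(x$var), lower = x$ci[, 1], upper = x$ci[, 2])
  cat("Robins-Wang MI estimates (m =", x$stack$m, "):\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export/import the imputer-analyst hand-off artifacts as CSV
#'
#' \code{S_mis} rows carry (subject i, imputation k) provenance; \code{D}
#' rows carry subject i.  These let an imputer process pass score
#' artifacts to a separate analyst process as flat files.
#'
#' @param bundle a \code{\link{build_score_bundle}} result.
#' @param dir directory to write \code{S_mis.csv} and \code{D.csv} into.
#' @export
write_score_bundle <- function(bundle, dir) {
  n <- bundle$n
  m <- bundle$m
  smis <- data.frame(subject = rep(seq_len(n), m),
                     imp = rep(seq_len(m), each = n), bundle$S_mis)
  utils::write.csv(smis, file.path(dir, "S_mis.csv"), row.names = FALSE)
  d <- data.frame(subject = seq_len(n), bundle$D)
  utils::write.csv(d, file.path(dir, "D.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_score_bundle
#' @param p dimension of theta (imputation covariates + 1).
#' @export
read_score_bundle <- function(dir, p) {
  smis <- utils::read.csv(file.path(dir, "S_mis.csv"))
  d <- utils::read.csv(file.path(dir, "D.csv"))
  n <- nrow(d)
  m <- nrow(smis) / n
  S_mis <- as.matrix(smis[order(smis$imp, smis$subject), -(1:2)])
  dimnames(S_mis) <- NULL
  D <- as.matrix(d[order(d$subject), -1, drop = FALSE])
  dimnames(D) <- NULL
  out <- list(S_mis = S_mis, s_obs = NULL, H_bar = NULL, D = D,
              n = n, m = m, p = p, theta = NULL)
  class(out) <- "score_bundle"
  out
}
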