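# Anthropometric data model used throughout the simulation laboratory:
#   sex ~ Bernoulli(pi)                          (0 = male, 1 = female)
#   (age, height) | sex ~ N(alpha0 + alpha1*sex, Sigma)
#   weight      = iota0 + iota1*sex + iota2*age + iota3*height + eta^sex * lambda * errW
#   loginsindex = beta0 + beta1*sex + beta2*age + beta3*weight + eta^sex * omega * errL
# with errW, errL mean-zero unit-variance errors and eta^sex meaning 1 for
# men and eta for women.  Parameter values below were estimated from a
# cohort of 951 young adults (ages in years, heights in metres, weights in
# kg, insulin index on the natural-log scale).

.base_params <- function() {
  list(
    pi      = 0.4577,
    alpha0  = c(25.02, 1.774),
    alpha1  = c(-0.03616, -0.1336),
    Sigma   = matrix(c(0.5521, 0.001574, 0.001574, 0.003705), 2, 2),
    iota    = c(-32.98, -2.314, -0.01566, 65.38),
    lambda_w = 12.29,
    beta_dgp = c(1.854, 0.2908, 0.08003, 0.01119),
    omega_l = 0.7887,
    eta     = 0.5
  )
}

.error_dists <- c("normal", "uniform", "t3", "t6",
                  "lognormal_mild", "lognormal_severe")

#' Build a named simulation scenario configuration
#'
#' Returns the full parameterization of one of the five study scenarios:
#' \describe{
#'   \item{\code{subgroup}}{Null sex effects everywhere (\code{alpha1 = 0},
#'     \code{iota1 = 0}, \code{beta1 = 0}, \code{eta = 1}); weight missing
#'     completely at random in men only; imputation model pools both sexes
#'     (covariates age, height, loginsindex) while the analysis regresses
#'     loginsindex on age and weight in men only.  The imputation and
#'     analysis models are incompatible: only the imputer assumes men and
#'     women are identically distributed.}
#'   \item{\code{heteroscedastic}}{Non-null sex effects and \code{eta = 1/2},
#'     so the error scale of weight and loginsindex in women is half that in
#'     men (variance one quarter).  Both models wrongly assume
#'     homoscedasticity.}
#'   \item{\code{interaction}}{Non-null sex effects, \code{eta = 1}; the
#'     analysis model adds an unnecessary weight-by-sex interaction (true
#'     coefficient 0), making it incompatible with the imputation model.}
#'   \item{\code{nonnormal}}{Null sex effects, \code{eta = 1}; the error
#'     distributions of weight and loginsindex are chosen via
#'     \code{variant} (both models are fitted to the whole sample and
#'     wrongly assume normal errors unless the variant is normal/normal).}
#'   \item{\code{mar_followup}}{Non-null sex effects, \code{eta = 1},
#'     compatible and correctly specified models, but weight is missing at
#'     random dependent on loginsindex, so the complete-case analysis is
#'     biased.}
#' }
#'
#' @param name scenario id, one of \code{"subgroup"}, \code{"heteroscedastic"},
#'   \code{"interaction"}, \code{"nonnormal"}, \code{"mar_followup"}.
#' @param n sample size per simulated dataset (>= 20).
#' @param p_obs marginal probability that weight is observed, in (0,1).
#' @param variant length-2 character vector \code{c(errW, errL)} of error
#'   distribution ids (see \code{\link{sample_standardized_error}});
#'   only accepted for the \code{nonnormal} scenario.
#' @param m number of imputations (default 50).
#' @param T_boot bootstrap replications for full mechanism bootstrapping
#'   (default 2500).
#' @param n_reps simulation replications (default 2500).
#' @param seed optional master seed stored in the configuration.
#' @return an object of class \code{scenario_config}.
#' @export
scenario_config <- function(name, n = 1000, p_obs = 0.4, variant = NULL,
                            m = 50, T_boot = 2500, n_reps = 2500,
                            seed = NULL) {
  name <- match.arg(name, c("subgroup", "heteroscedastic", "interaction",
                            "nonnormal", "mar_followup"))
  stopifnot(n >= 20, p_obs > 0, p_obs < 1, m >= 1)
  if (!is.null(variant) && name != "nonnormal")
    stop("error-distribution variants are only accepted for the 'nonnormal' scenario")
  cfg <- .base_params()
  cfg$name <- name
  cfg$n <- as.integer(n)
  cfg$p_obs <- p_obs
  cfg$m <- as.integer(m)
  cfg$T_boot <- as.integer(T_boot)
  cfg$n_reps <- as.integer(n_reps)
  cfg$seed <- seed
  cfg$error_w_dist <- "normal"
  cfg$error_l_dist <- "normal"
  cfg$outcome <- "loginsindex"

  null_means <- function(cfg) {
    cfg$alpha1 <- c(0, 0)
    cfg$iota[2] <- 0
    cfg$beta_dgp[2] <- 0
    cfg
  }
  full_covars <- c("const", "sex", "age", "height", "loginsindex")

  if (name == "subgroup") {
    cfg <- null_means(cfg)
    cfg$eta <- 1
    cfg$mdm <- "mcar_men_only"
    cfg$imputation_covariates <- c("const", "age", "height", "loginsindex")
    cfg$analysis_covariates <- c("const", "age", "weight")
    cfg$analysis_subgroup <- "men"
  } else if (name == "heteroscedastic") {
    cfg$eta <- 0.5
    cfg$mdm <- "mcar_all"
    cfg$imputation_covariates <- full_covars
    cfg$analysis_covariates <- c("const", "sex", "age", "weight")
    cfg$analysis_subgroup <- "all"
  } else if (name == "interaction") {
    cfg$eta <- 1
    cfg$mdm <- "mcar_all"
    cfg$imputation_covariates <- full_covars
    cfg$analysis_covariates <- c("const", "sex", "age", "weight", "weight:sex")
    cfg$analysis_subgroup <- "all"
  } else if (name == "nonnormal") {
    cfg <- null_means(cfg)
    cfg$eta <- 1
    cfg$mdm <- "mcar_all"
    cfg$imputation_covariates <- c("const", "age", "height", "loginsindex")
    cfg$analysis_covariates <- c("const", "age", "weight")
    cfg$analysis_subgroup <- "all"
    if (!is.null(variant)) {
      stopifnot(length(variant) == 2)
      cfg$error_w_dist <- match.arg(variant[1], .error_dists)
      cfg$error_l_dist <- match.arg(variant[2], .error_dists)
    }
  } else { # mar_followup
    cfg$eta <- 1
    cfg$mdm <- "mar_on_loginsindex"
    cfg$imputation_covariates <- full_covars
    cfg$analysis_covariates <- c("const", "sex", "age", "weight")
    cfg$analysis_subgroup <- "all"
  }
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration:", x$name, "\n")
  cat("  n =", x$n, " p_obs =", x$p_obs, " mdm =", x$mdm, "\n")
  cat("  eta =", x$eta, " errors =", x$error_w_dist, "/", x$error_l_dist, "\n")
  cat("  imputation covariates:", paste(x$imputation_covariates, collapse = ", "), "\n")
  cat("  analysis:", x$outcome, "~",
      paste(x$analysis_covariates, collapse = " + "),
      if (x$analysis_subgroup == "men") "[men only]" else "", "\n")
  invisible(x)
}

#' Draw standardized errors from a named base distribution
#'
#' All distributions are location-scale standardized in closed form to mean
#' zero and unit variance: uniform on \eqn{[-\sqrt3, \sqrt3]}; Student's t
#' with df degrees of freedom divided by \eqn{\sqrt{df/(df-2)}}; lognormal
#' \eqn{\exp\{N(0, s^2)\}} centred by \eqn{e^{s^2/2}} and scaled by
#' \eqn{\sqrt{(e^{s^2}-1)e^{s^2}}}, with \eqn{s = 1/4} (mild) or
#' \eqn{s = 1} (severe).
#'
#' @param dist one of \code{"normal"}, \code{"uniform"}, \code{"t3"},
#'   \code{"t6"}, \code{"lognormal_mild"}, \code{"lognormal_severe"}.
#' @param size number of draws.
#' @return numeric vector of length \code{size}.
#' @export
sample_standardized_error <- function(dist, size) {
  dist <- match.arg(dist, .error_dists)
  stopifnot(size >= 1)
  switch(dist,
    normal  = stats::rnorm(size),
    uniform = stats::runif(size, -sqrt(3), sqrt(3)),
    t3      = .standardized_t(3, size),
    t6      = .standardized_t(6, size),
    lognormal_mild   = .standardized_lnorm(1 / 4, size),
    lognormal_severe = .standardized_lnorm(1, size)
  )
}

.standardized_t <- function(df, size) {
  if (df <= 2) stop("t-distribution with df <= 2 has undefined variance")
  stats::rt(size, df) / sqrt(df / (df - 2))
}

.standardized_lnorm <- function(s, size) {
  (exp(stats::rnorm(size, 0, s)) - exp(s^2 / 2)) /
    sqrt((exp(s^2) - 1) * exp(s^2))
}

#' Generate a complete dataset from the anthropometric model
#'
#' Uses the current RNG stream.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return a \code{data.frame} with columns \code{sex}, \code{age},
#'   \code{height}, \code{weight}, \code{loginsindex} and no missing values.
#' @export
generate_complete <- function(config) {
  n <- config$n
  sex <- stats::rbinom(n, 1, config$pi)
  # bivariate normal via Cholesky of Sigma
  L <- chol(config$Sigma)
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
  mu <- matrix(config$alpha0, n, 2, byrow = TRUE) +
    outer(sex, config$alpha1)
  age <- mu[, 1] + z[, 1]
  height <- mu[, 2] + z[, 2]
  scale_sex <- ifelse(sex == 1, config$eta, 1)
  errW <- sample_standardized_error(config$error_w_dist, n)
  errL <- sample_standardized_error(config$error_l_dist, n)
  io <- config$iota
  weight <- io[1] + io[2] * sex + io[3] * age + io[4] * height +
    scale_sex * config$lambda_w * errW
  bd <- config$beta_dgp
  loginsindex <- bd[1] + bd[2] * sex + bd[3] * age + bd[4] * weight +
    scale_sex * config$omega_l * errL
  data.frame(sex = sex, age = age, height = height,
             weight = weight, loginsindex = loginsindex)
}

#' Construct an incomplete dataset from user data
#'
#' @param data data.frame with missing values (NA) confined to
#'   \code{missing_col}.
#' @param missing_col name of the single incompletely observed column.
#' @return object of class \code{incomplete_data} with fields \code{data},
#'   observation indicator \code{r} (1 = observed), missing count \code{t}.
#' @export
as_incomplete <- function(data, missing_col = "weight") {
  stopifnot(is.data.frame(data), missing_col %in% names(data))
  other <- setdiff(names(data), missing_col)
  if (any(vapply(data[other], anyNA, logical(1))))
    stop("missing values are only supported in column '", missing_col, "'")
  r <- as.integer(!is.na(data[[missing_col]]))
  out <- list(data = data, r = r, t = sum(r == 0L), n = nrow(data),
              missing_col = missing_col)
  class(out) <- "incomplete_data"
  out
}

#' @export
print.incomplete_data <- function(x, ...) {
  cat("Incomplete dataset: n =", x$n, "rows,", x$t, "missing in '",
      x$missing_col, "'\n")
  invisible(x)
}

#' Impose the configured missing data mechanism on a complete dataset
#'
#' Mechanisms: \code{mcar_all} observes each weight independently with
#' probability \code{p_obs}; \code{mcar_men_only} always observes women and
#' observes men with probability \code{p_obs}; \code{mar_on_loginsindex}
#' observes with probability \code{expit(psi0 + z)} where \code{z} is the
#' standardized loginsindex and \code{psi0} is solved numerically so the
#' marginal observation probability equals \code{p_obs}.
#'
#' @param data complete data.frame from \code{\link{generate_complete}}.
#' @param config a \code{\link{scenario_config}}.
#' @param on_degenerate what to do if all or none of the weights end up
#'   missing: \code{"error"} (default, user-data mode) or
#'   \code{"resample"} (redraw the indicator up to 100 times).
#' @return an \code{\link{as_incomplete}} object with weight masked.
#' @export
apply_mdm <- function(data, config, on_degenerate = c("error", "resample")) {
  on_degenerate <- match.arg(on_degenerate)
  n <- nrow(data)
  p_mask <- switch(config$mdm,
    mcar_all = rep(config$p_obs, n),
    mcar_men_only = ifelse(data$sex == 1, 1, config$p_obs),
    mar_on_loginsindex = .mar_probs(data$loginsindex, config$p_obs),
    stop("unknown missing data mechanism: ", config$mdm)
  )
  for (attempt in seq_len(101)) {
    r <- stats::rbinom(n, 1, p_mask)
    t_mis <- n - sum(r)
    if (t_mis > 0 && t_mis < n) break
    if (on_degenerate == "error" || attempt > 100)
      stop("degenerate missingness pattern (t = ", t_mis, " of n = ", n, ")")
  }
  masked <- data
  masked$weight[r == 0] <- NA_real_
  out <- as_incomplete(masked, "weight")
  out$r <- as.integer(r)
  out$t <- t_mis
  out
}

# P(observed) = expit(psi0 + z), z the standardized outcome; psi0 calibrated
# by root-finding so the marginal observation probability equals p_obs.
.mar_probs <- function(loginsindex, p_obs, slope = 1) {
  z <- (loginsindex - mean(loginsindex)) / stats::sd(loginsindex)
  f <- function(psi0) mean(stats::plogis(psi0 + slope * z)) - p_obs
  psi0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  stats::plogis(psi0 + slope * z)
}

#' Write an incomplete dataset and its configuration to disk
#'
#' The data are written as CSV with a header row and missing weights as
#' empty fields; the configuration sidecar is JSON-style key-value text.
#'
#' @param x an \code{incomplete_data} object.
#' @param file CSV path; the sidecar is written to \code{paste0(file, ".config.json")}
#'   when \code{config} is supplied.
#' @param config optional \code{scenario_config} to record alongside.
#' @export
write_incomplete_csv <- function(x, file, config = NULL) {
  utils::write.csv(x$data, file, row.names = FALSE, na = "")
  if (!is.null(config)) {
    flat <- lapply(unclass(config), function(v) if (is.matrix(v)) as.vector(v) else v)
    txt <- paste0(
      "{\n",
      paste0('  "', names(flat), '": ',
             vapply(flat, function(v) {
               if (is.null(v)) return("null")
               if (is.character(v)) {
                 s <- paste0('"', v, '"')
               } else s <- format(v, digits = 15)
               if (length(s) > 1) paste0("[", paste(s, collapse = ", "), "]") else s
             }, character(1)),
             collapse = ",\n"),
      "\n}\n")
    writeLines(txt, paste0(file, ".config.json"))
  }
  invisible(file)
}
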