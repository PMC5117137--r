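# Simulation orchestration: replicate a scenario across methods, compute
# bias / empirical variance / mean estimated variance / coverage / CI
# width, with per-replication seed substreams so that methods are
# stream-isolated and any execution order gives identical aggregates.

#' Monte Carlo standard error of an estimated coverage probability
#'
#' @param p true coverage probability in (0,1).
#' @param reps number of simulation replications.
#' @return \eqn{\sqrt{p(1-p)/reps}}.
#' @export
mc_se_coverage <- function(p, reps) {
  stopifnot(p > 0, p < 1, reps >= 1)
  sqrt(p * (1 - p) / reps)
}

#' Acceptance band for an estimated coverage probability
#'
#' The interval \eqn{p \mp z_{(1+conf)/2}\sqrt{p(1-p)/reps}}, rounded to
#' three decimals for reporting.
#'
#' @inheritParams mc_se_coverage
#' @param conf band confidence (default 0.95).
#' @return named vector \code{c(lower, upper)}.
#' @export
coverage_band <- function(p, reps, conf = 0.95) {
  se <- mc_se_coverage(p, reps)
  z <- stats::qnorm((1 + conf) / 2)
  round(c(lower = p - z * se, upper = p + z * se), 3)
}

#' True analysis-model coefficients implied by a scenario configuration
#'
#' The weight coefficient is always \code{beta3} of the data model; the
#' sex, age and intercept coefficients are the corresponding model
#' parameters (with sex terms absent under subgroup analysis, where the
#' male stratum has no sex contrasts); an included weight-by-sex
#' interaction has true coefficient 0.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return named vector aligned with \code{config$analysis_covariates}.
#' @export
true_beta <- function(config) {
  bd <- config$beta_dgp
  vals <- c(const = bd[1], sex = bd[2], age = bd[3], weight = bd[4],
            "weight:sex" = 0)
  out <- vals[config$analysis_covariates]
  names(out) <- config$analysis_covariates
  if (anyNA(out)) stop("no known truth for some analysis covariate")
  out
}

.rep_seed <- function(master, r, offset = 0L) {
  (as.integer(master) + 7919L * as.integer(r) + as.integer(offset)) %%
    2147480000L
}

#' Run a simulation scenario across inference methods
#'
#' For each replication: generate a complete dataset, impose missingness,
#' run each requested method, and record the estimate, variance estimate
#' and confidence interval per coefficient.  Aggregates follow the usual
#' simulation-study metrics: mean bias, empirical variance of the
#' estimates, mean of the estimated variances, empirical coverage of the
#' level-\code{level} interval and mean interval width.
#'
#' Reproducibility: replication r derives its own seed from
#' \code{(seed, r)}; each method draws from its own substream, so adding
#' or removing a method never changes another method's results, and any
#' execution order gives identical aggregates.  \code{rubin} and
#' \code{rubin_robust} intentionally share one substream (they pool the
#' same imputations; only the within-variance flavour differs).
#'
#' @param config a \code{\link{scenario_config}}; \code{config$n_reps}
#'   replications are run with \code{config$m} imputations.
#' @param methods subset of \code{c("rubin", "rubin_robust", "rw", "fmb")}.
#' @param seed master seed (defaults to \code{config$seed}).
#' @param level confidence level (default 0.95).
#' @param fmb_ci FMB interval flavour used for the coverage/width columns
#'   (default \code{"percentile"}).
#' @param fmb_mdm_mode FMB missingness re-imposition mode.
#' @return object of class \code{sim_summary}: a tidy data.frame
#'   \code{$summary} with one row per method x coefficient, plus failure
#'   counts and the configuration echo.
#' @export
run_scenario <- function(config, methods = c("rubin", "rubin_robust", "rw", "fmb"),
                         seed = config$seed, level = 0.95,
                         fmb_ci = "percentile",
                         fmb_mdm_mode = c("observed_mdp", "modelled")) {
  methods <- match.arg(methods, c("rubin", "rubin_robust", "rw", "fmb"),
                       several.ok = TRUE)
  fmb_mdm_mode <- match.arg(fmb_mdm_mode)
  if (is.null(seed)) stop("a master seed is required for a simulation run")
  n_reps <- config$n_reps
  truth <- true_beta(config)
  q <- length(truth)
  offsets <- c(data = 0L, rubin = 1L, rubin_robust = 1L, rw = 2L, fmb = 3L)

  record <- function() array(NA_real_, c(n_reps, q, 4),
                             dimnames = list(NULL, config$analysis_covariates,
                                             c("est", "var", "lo", "hi")))
  res <- lapply(stats::setNames(methods, methods), function(m) record())
  fails <- stats::setNames(integer(length(methods)), methods)

  need_rubin <- any(c("rubin", "rubin_robust") %in% methods)
  for (r in seq_len(n_reps)) {
    set.seed(.rep_seed(seed, r, offsets[["data"]]))
    idata <- apply_mdm(generate_complete(config), config,
                       on_degenerate = "resample")
    if (need_rubin) {
      set.seed(.rep_seed(seed, r, offsets[["rubin"]]))
      fit <- tryCatch(
        rubin_mi(idata, config$imputation_covariates, config$outcome,
                 config$analysis_covariates, config$analysis_subgroup,
                 m = config$m, level = level),
        error = function(e) NULL)
      for (variant in intersect(c("rubin", "rubin_robust"), methods)) {
        if (is.null(fit)) { fails[variant] <- fails[variant] + 1L; next }
        est <- if (variant == "rubin") fit$standard else fit$robust
        res[[variant]][r, , ] <- cbind(est$beta, est$V, est$ci)
      }
    }
    if ("rw" %in% methods) {
      set.seed(.rep_seed(seed, r, offsets[["rw"]]))
      fit <- tryCatch(
        rw_mi(idata, config$imputation_covariates, config$outcome,
              config$analysis_covariates, config$analysis_subgroup,
              m = config$m, level = level),
        error = function(e) NULL)
      if (is.null(fit)) fails["rw"] <- fails["rw"] + 1L
      else res[["rw"]][r, , ] <- cbind(fit$beta, fit$var, fit$ci)
    }
    if ("fmb" %in% methods) {
      set.seed(.rep_seed(seed, r, offsets[["fmb"]]))
      out <- tryCatch({
        est <- fmb_estimate(idata, config$imputation_covariates,
                            config$outcome, config$analysis_covariates,
                            config$analysis_subgroup)
        boot <- fmb_bootstrap(est, mdm_mode = fmb_mdm_mode,
                              T = config$T_boot)
        cbind(est$beta, bootstrap_variance(boot),
              bootstrap_interval(boot, fmb_ci, level))
      }, error = function(e) NULL)
      if (is.null(out)) fails["fmb"] <- fails["fmb"] + 1L
      else res[["fmb"]][r, , ] <- out
    }
  }

  rows <- list()
  for (meth in methods) {
    a <- res[[meth]]
    for (j in seq_len(q)) {
      est <- a[, j, "est"]
      ok <- !is.na(est)
      cover <- a[ok, j, "lo"] <= truth[j] & truth[j] <= a[ok, j, "hi"]
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, coef = config$analysis_covariates[j],
        truth = unname(truth[j]),
        bias = mean(est[ok]) - truth[j],
        emp_var = stats::var(est[ok]),
        mean_var = mean(a[ok, j, "var"]),
        coverage = mean(cover),
        mean_width = mean(a[ok, j, "hi"] - a[ok, j, "lo"]),
        n_ok = sum(ok))
    }
  }
  summary <- do.call(rbind, rows)
  row.names(summary) <- NULL
  out <- list(summary = summary, failures = fails, config = config,
              level = level, n_reps = n_reps, seed = seed,
              mc_se = mc_se_coverage(level, n_reps),
              replicates = res)
  class(out) <- "sim_summary"
  out
}

#' @export
print.sim_summary <- function(x, digits = 4, ...) {
  cat("Simulation:", x$config$name, " n =", x$config$n,
      " p_obs =", x$config$p_obs, " reps =", x$n_reps,
      " m =", x$config$m, "\n")
  cat("Coverage MC-SE at", x$level, ":", signif(x$mc_se, 3), "\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  if (any(x$failures > 0)) cat("Failures:", paste(names(x$failures),
      x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation summary as tidy CSV
#' @param x a \code{\link{run_scenario}} result.
#' @param file output path.
#' @export
write_sim_summary <- function(x, file) {
  long <- stats::reshape(x$summary, direction = "long",
                         varying = list(c("bias", "emp_var", "mean_var",
                                          "coverage", "mean_width")),
                         v.names = "value",
                         times = c("bias", "emp_var", "mean_var",
                                   "coverage", "mean_width"),
                         timevar = "metric",
                         idvar = c("method", "coef"))
  long <- long[, c("method", "coef", "metric", "value")]
  long$scenario <- x$config$name
  utils::write.csv(long[, c("scenario", "method", "coef", "metric", "value")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Imputation inference for a user-supplied incomplete dataset
#'
#' One-call interface: declare the incomplete column, the imputation-model
#' and analysis-model covariates, pick a method, and get a coefficient
#' table with standard errors and confidence intervals.
#'
#' @param data data.frame with NAs confined to \code{missing_col}.
#' @param missing_col the single incompletely observed column.
#' @param imp_covariates imputation-model terms (include \code{"const"}).
#' @param outcome analysis response column.
#' @param analysis_covariates analysis-model terms.
#' @param method one of \code{"rubin"}, \code{"rubin_robust"},
#'   \code{"rw"}, \code{"fmb"}.
#' @param m imputations (MI methods).
#' @param T_boot bootstrap replications (FMB).
#' @param subgroup analysis row filter.
#' @param level confidence level.
#' @param seed optional seed.
#' @param fmb_ci FMB interval flavour.
#' @param fmb_mdm_mode FMB missingness re-imposition mode.
#' @return data.frame with columns coef, estimate, se, lower, upper.
#' @export
impute_infer <- function(data, missing_col, imp_covariates, outcome,
                         analysis_covariates,
                         method = c("rubin", "rubin_robust", "rw", "fmb"),
                         m = 50, T_boot = 2500, subgroup = NULL,
                         level = 0.95, seed = NULL,
                         fmb_ci = "percentile",
                         fmb_mdm_mode = "observed_mdp") {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  idata <- as_incomplete(data, missing_col)
  if (idata$t == 0 || idata$t == idata$n)
    stop("imputation requires 0 < number missing < n")
  if (method %in% c("rubin", "rubin_robust")) {
    fit <- rubin_mi(idata, imp_covariates, outcome, analysis_covariates,
                    subgroup, m = m, level = level)
    est <- if (method == "rubin") fit$standard else fit$robust
    beta <- est$beta; se <- sqrt(est$V); ci <- est$ci
  } else if (method == "rw") {
    fit <- rw_mi(idata, imp_covariates, outcome, analysis_covariates,
                 subgroup, m = m, level = level)
    beta <- fit$beta; se <- sqrt(fit$var); ci <- fit$ci
  } else {
    est <- fmb_estimate(idata, imp_covariates, outcome, analysis_covariates,
                        subgroup)
    boot <- fmb_bootstrap(est, mdm_mode = fmb_mdm_mode, T = T_boot)
    beta <- est$beta; se <- sqrt(bootstrap_variance(boot))
    ci <- bootstrap_interval(boot, fmb_ci, level)
  }
  data.frame(coef = analysis_covariates, estimate = beta, se = se,
             lower = ci[, 1], upper = ci[, 2], row.names = NULL)
}
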