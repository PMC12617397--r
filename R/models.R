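#' Specification for the confirmatory mixed models
#'
#' The confirmatory model regresses an outcome on log-RMSSD with age,
#' gender, BMI and device type as covariates and a random intercept for
#' country, estimated by REML.
#'
#' @param outcome outcome column name.
#' @param fixed fixed-effect column names.
#' @param cluster clustering factor (random intercept).
#' @param alpha significance level (default 0.05).
#' @param n_tests number of tests in the family for Bonferroni adjustment.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome,
                       fixed = c("log_rmssd", "age", "gender", "bmi",
                                 "device"),
                       cluster = "country", alpha = 0.05, n_tests = 7) {
  structure(list(outcome = outcome, fixed = fixed, cluster = cluster,
                 alpha = alpha, n_tests = n_tests), class = "model_spec")
}

#' Fit a random-intercept linear mixed model
#'
#' REML fit of `outcome ~ fixed effects + (1 | cluster)` with
#' Satterthwaite-approximated per-coefficient degrees of freedom. Singular
#' fits (cluster variance estimated at zero) are reported through the
#' `singular` flag, not treated as failures.
#'
#' @param data a complete data frame.
#' @param spec a [model_spec()] (or an outcome name, with the default spec).
#' @return A list of class `lmm_fit`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `df`, `t`, `p`), `sigma2_cluster`,
#'   `sigma2_residual`, `icc`, `r2_conditional`, `var_fixed`, `n`,
#'   `singular`, `spec`.
#' @export
fit_lmm <- function(data, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  keep <- spec$fixed[vapply(spec$fixed, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  dropped <- setdiff(spec$fixed, keep)
  if (length(dropped)) {
    warning("dropping constant predictor(s): ", paste(dropped, collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    spec$outcome, "~", paste(keep, collapse = " + "),
    "+ (1 |", spec$cluster, ")"))
  fit <- suppressMessages(lmerTest::lmer(
    fml, data = data, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  sm <- suppressWarnings(summary(fit))$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"], df = sm[, "df"], t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"], row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2c <- vc$vcov[vc$grp == spec$cluster]
  s2e <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(drop(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  structure(list(
    coefficients = coefs,
    sigma2_cluster = s2c, sigma2_residual = s2e,
    icc = compute_icc(s2c, s2e),
    r2_conditional = (var_fixed + s2c) / (var_fixed + s2c + s2e),
    var_fixed = var_fixed,
    n = stats::nobs(fit),
    singular = lme4::isSingular(fit),
    spec = spec
  ), class = "lmm_fit")
}

#' Intraclass correlation from variance components
#'
#' `ICC = sigma2_cluster / (sigma2_cluster + sigma2_residual)`: the share of
#' outcome variance attributable to between-cluster differences.
#'
#' @param fit an `lmm_fit`, or the cluster variance component.
#' @param sigma2_residual residual variance (when `fit` is a variance).
#' @return ICC in `[0, 1]`; `NaN` when both variances are 0.
#' @export
compute_icc <- function(fit, sigma2_residual = NULL) {
  if (inherits(fit, "lmm_fit")) {
    s2c <- fit$sigma2_cluster
    s2e <- fit$sigma2_residual
  } else {
    s2c <- fit
    s2e <- sigma2_residual
  }
  if (s2c < 0 || s2e < 0) stop("variance components must be >= 0")
  s2c / (s2c + s2e)
}

#' Conditional R-squared of a Gaussian mixed model
#'
#' Variance-decomposition definition: the variance of the fixed-effect
#' linear predictor plus the cluster variance, over that sum plus the
#' residual variance; the share of variance explained jointly by fixed and
#' random effects.
#'
#' @param fit an `lmm_fit`.
#' @return Proportion in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  (fit$var_fixed + fit$sigma2_cluster) /
    (fit$var_fixed + fit$sigma2_cluster + fit$sigma2_residual)
}

#' Pool coefficient estimates across imputations by Rubin's rules
#'
#' Combines m estimates of the same coefficient: the pooled estimate is the
#' mean `Qbar`; the within-imputation variance `W` is the mean squared
#' standard error; the between-imputation variance `B` is the sample
#' variance of the estimates; the total variance is `T = W + (1 + 1/m) B`.
#' Degrees of freedom use the Barnard-Rubin small-sample adjustment with the
#' average complete-data df.
#'
#' @param estimates numeric vector of m coefficient estimates.
#' @param variances numeric vector of m squared standard errors.
#' @param df_complete complete-data degrees of freedom (scalar or vector).
#' @return A list of class `pooled_estimate`: `estimate`, `within`,
#'   `between`, `total`, `se`, `df`, `t`, `p`, `m`.
#' @examples
#' pool_rubin(c(1, 2, 3), c(1, 1, 1), df_complete = 100)
#' @export
pool_rubin <- function(estimates, variances, df_complete) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool")
  if (length(variances) != m) stop("estimates and variances differ in length")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  dfcom <- mean(df_complete)
  lambda <- (1 + 1 / m) * b / total
  df <- if (lambda < 1e-10) {
    dfcom
  } else {
    df_old <- (m - 1) / lambda^2
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  }
  se <- sqrt(total)
  t <- qbar / se
  structure(list(
    estimate = qbar, within = w, between = b, total = total,
    se = se, df = df, t = t,
    p = 2 * stats::pt(-abs(t), df), m = m
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> B = %.4g, SE = %.4g, t(%.2f) = %.3g, p = %.4g (m = %d)\n",
    x$estimate, x$se, x$df, x$t, x$p, x$m))
  invisible(x)
}

#' Fit a mixed model on each imputed dataset and pool one coefficient
#'
#' Convenience wrapper: fits the model of `spec` on every completed dataset
#' and Rubin-pools the coefficient matching `term`, together with averaged
#' ICC and conditional R-squared.
#'
#' @param imputed an `imputed_datasets` object (or a list of data frames).
#' @param spec a [model_spec()] or outcome name.
#' @param term coefficient name to pool (default `"log_rmssd"`).
#' @return A `pooled_estimate` with extra fields `icc`, `r2_conditional`
#'   (averages over imputations) and `term`.
#' @export
pool_lmm <- function(imputed, spec, term = "log_rmssd") {
  datasets <- if (inherits(imputed, "imputed_datasets")) imputed$datasets
              else imputed
  fits <- lapply(datasets, fit_lmm, spec = spec)
  rows <- lapply(fits, function(f) {
    r <- f$coefficients[f$coefficients$term == term, ]
    if (!nrow(r)) stop("term not found in fit: ", term)
    r
  })
  est <- vapply(rows, `[[`, numeric(1), "estimate")
  v <- vapply(rows, `[[`, numeric(1), "se")^2
  dfc <- vapply(rows, `[[`, numeric(1), "df")
  out <- pool_rubin(est, v, dfc)
  out$icc <- mean(vapply(fits, `[[`, numeric(1), "icc"))
  out$r2_conditional <- mean(vapply(fits, `[[`, numeric(1), "r2_conditional"))
  out$term <- term
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, k * p)` for a family of `k` tests.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param k family size (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, k) {
  if (k < 1) stop("k must be >= 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]")
  }
  pmin(1, k * p_values)
}

#' Country-specific general linear model
#'
#' Ordinary least squares on a single-country subset with the same
#' predictors as the pooled mixed model; predictors constant within the
#' country (e.g. device type where only one device was used) are dropped
#' with a warning.
#'
#' @param data the full data frame.
#' @param country the country level to subset.
#' @param spec a [model_spec()] or outcome name.
#' @return A list of class `country_glm`: `coefficients` (term, estimate,
#'   se, t, df, p, p_bonferroni), `country`, `dropped`, `n`.
#' @export
fit_country_glm <- function(data, country, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  d <- droplevels(data[data[[spec$cluster]] == country, , drop = FALSE])
  if (!nrow(d)) stop("no rows for country: ", country)
  keep <- spec$fixed[vapply(spec$fixed, function(v)
    length(unique(d[[v]][!is.na(d[[v]])])) > 1, logical(1))]
  dropped <- setdiff(spec$fixed, keep)
  if (length(dropped)) {
    warning(sprintf("constant predictor(s) dropped in %s: %s", country,
                    paste(dropped, collapse = ", ")))
  }
  fml <- stats::reformulate(keep, response = spec$outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2], t = sm[, 3],
    df = fit$df.residual, p = sm[, 4], row.names = NULL
  )
  coefs$p_bonferroni <- bonferroni_adjust(coefs$p, spec$n_tests)
  structure(list(coefficients = coefs, country = country, dropped = dropped,
                 n = nrow(d)), class = "country_glm")
}
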