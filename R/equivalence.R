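#' Median split of log-RMSSD
#'
#' Dichotomizes participants into Low- and High-HRV groups at the sample
#' median of log-RMSSD: values strictly above the median are High, values at
#' or below the median are Low. The median is computed once on the full
#' analysis sample (log-RMSSD carries no missingness in the analysis set).
#'
#' @param log_rmssd numeric vector with at least 2 distinct values.
#' @return Factor with levels `Low`, `High` (reference `Low`).
#' @export
median_split <- function(log_rmssd) {
  if (anyNA(log_rmssd)) stop("log_rmssd must be complete")
  if (length(unique(log_rmssd)) < 2) {
    stop("all values identical; median split undefined")
  }
  med <- stats::median(log_rmssd)
  factor(ifelse(log_rmssd > med, "High", "Low"), levels = c("Low", "High"))
}

#' Smallest effect sizes of interest (SESOI) specification
#'
#' Equivalence bounds are defined as +/- `fraction` of each outcome's
#' maximum possible score: with the default 5% fraction this gives +/-3 for
#' DERS (max 60), +/-1.35 for the embedded PHQ-A (max 27), +/-1.05 for the
#' GAD-7 (max 21), +/-3.75 for the MMAPP total (max 75), +/-1.20 for DBIS
#' (max 24), and +/-5 for the two percentage outcomes (max 100).
#'
#' @param fraction the SESOI fraction (default 0.05).
#' @param scale_max named vector of maximum scores per outcome.
#' @return A list of class `sesoi_spec`.
#' @export
sesoi_spec <- function(fraction = 0.05,
                       scale_max = c(ders = 60, mmapp_phqa = 27,
                                     mmapp_gad7 = 21, mmapp_total = 75,
                                     dbis = 24, false_alarm_pct = 100,
                                     immediate_reward_pct = 100)) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  structure(list(fraction = fraction, scale_max = scale_max),
            class = "sesoi_spec")
}

#' Equivalence bounds for one outcome
#'
#' @param outcome outcome name present in the SESOI specification.
#' @param spec a [sesoi_spec()].
#' @return Numeric vector `c(lower, upper)` = -/+ fraction * scale maximum.
#' @examples
#' sesoi_bounds("ders")        # -3, 3
#' sesoi_bounds("mmapp_gad7")  # -1.05, 1.05
#' @export
sesoi_bounds <- function(outcome, spec = sesoi_spec()) {
  if (!outcome %in% names(spec$scale_max)) {
    stop("no SESOI scale maximum for outcome: ", outcome)
  }
  delta <- spec$fraction * spec$scale_max[[outcome]]
  c(lower = -delta, upper = delta)
}

#' Two one-sided tests (TOST) for equivalence
#'
#' Tests whether a group difference is bounded within `(lower, upper)`:
#' `tL = (B - lower) / SE` with `pL = P(T_df >= tL)` (difference above the
#' lower bound) and `tU = (B - upper) / SE` with `pU = P(T_df <= tU)`
#' (difference below the upper bound). Equivalence is concluded when both
#' p-values fall below `alpha`; at `alpha = 0.05` this is identical to the
#' 90% confidence interval lying inside the bounds.
#'
#' @param estimate pooled group difference `B` (High minus Low).
#' @param se standard error (> 0).
#' @param df degrees of freedom (> 0).
#' @param bounds numeric `c(lower, upper)` with `lower < upper`.
#' @param alpha one-sided significance level (default 0.05).
#' @return A list of class `equivalence_result`: `estimate`, `se`, `df`,
#'   `lower`, `upper`, `t_lower`, `t_upper`, `p_lower`, `p_upper`, `ci90`,
#'   `equivalent`.
#' @examples
#' tost(1.62, 0.58, 1090.52, c(-3, 3))   # equivalent
#' @export
tost <- function(estimate, se, df, bounds, alpha = 0.05) {
  if (se <= 0) stop("se must be > 0")
  if (df <= 0) stop("df must be > 0")
  lower <- bounds[[1]]
  upper <- bounds[[2]]
  if (!(lower < upper)) stop("bounds must satisfy lower < upper")
  t_lower <- (estimate - lower) / se
  t_upper <- (estimate - upper) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  structure(list(
    estimate = estimate, se = se, df = df,
    lower = lower, upper = upper,
    t_lower = t_lower, t_upper = t_upper,
    p_lower = p_lower, p_upper = p_upper,
    ci90 = ci90(estimate, se, df),
    equivalent = p_lower < alpha && p_upper < alpha
  ), class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    paste0("<equivalence_result> B = %.3g, 90%% CI [%.3g, %.3g], ",
           "bounds [%.3g, %.3g]: %s\n"),
    x$estimate, x$ci90[1], x$ci90[2], x$lower, x$upper,
    if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' 90% confidence interval around a pooled estimate
#'
#' `B +/- t(0.95, df) * SE`; the interval that agrees with the TOST verdict
#' at alpha = 0.05.
#'
#' @param estimate point estimate.
#' @param se standard error (> 0).
#' @param df degrees of freedom.
#' @return Numeric `c(lower, upper)`.
#' @export
ci90 <- function(estimate, se, df) {
  if (se <= 0) stop("se must be > 0")
  half <- stats::qt(0.95, df) * se
  c(estimate - half, estimate + half)
}

#' Run the full equivalence suite over imputed datasets
#'
#' For each outcome: participants are dichotomized by a median split of
#' log-RMSSD (computed once, on the first completed dataset); the
#' confirmatory mixed model is refitted with the group factor (reference =
#' Low) in place of continuous log-RMSSD on every imputed dataset; the
#' High-Low coefficient is Rubin-pooled; and the TOST procedure and 90% CI
#' are applied against the SESOI bounds.
#'
#' @param imputed an `imputed_datasets` object or list of completed data
#'   frames (each containing `log_rmssd`).
#' @param outcomes outcome columns to test (default: the seven
#'   pre-registered outcomes).
#' @param sesoi a [sesoi_spec()].
#' @param covariates fixed-effect covariates retained alongside the group
#'   factor.
#' @param cluster clustering factor.
#' @param alpha significance level.
#' @return A data frame with one row per outcome: `outcome`, `B`, `ci90_lo`,
#'   `ci90_hi`, `SE`, `df`, `delta_lower`, `delta_upper`, `t_lower`,
#'   `t_upper`, `p_lower`, `p_upper`, `verdict`.
#' @export
run_equivalence_suite <- function(imputed,
                                  outcomes = c("ders", "false_alarm_pct",
                                               "immediate_reward_pct",
                                               "mmapp_gad7", "mmapp_phqa",
                                               "mmapp_total", "dbis"),
                                  sesoi = sesoi_spec(),
                                  covariates = c("age", "gender", "bmi",
                                                 "device"),
                                  cluster = "country", alpha = 0.05) {
  datasets <- if (inherits(imputed, "imputed_datasets")) imputed$datasets
              else imputed
  grp <- median_split(datasets[[1]]$log_rmssd)
  datasets <- lapply(datasets, function(d) {
    d$hrv_group <- grp
    d
  })
  rows <- lapply(outcomes, function(oc) {
    spec <- model_spec(oc, fixed = c("hrv_group", covariates),
                       cluster = cluster, alpha = alpha)
    pooled <- pool_lmm(datasets, spec, term = "hrv_groupHigh")
    eq <- tost(pooled$estimate, pooled$se, pooled$df, sesoi_bounds(oc, sesoi),
               alpha = alpha)
    data.frame(
      outcome = oc, B = eq$estimate, ci90_lo = eq$ci90[1],
      ci90_hi = eq$ci90[2], SE = eq$se, df = eq$df,
      delta_lower = eq$lower, delta_upper = eq$upper,
      t_lower = eq$t_lower, t_upper = eq$t_upper,
      p_lower = eq$p_lower, p_upper = eq$p_upper,
      verdict = if (eq$equivalent) "equivalent" else "not_equivalent",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
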