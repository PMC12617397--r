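#' Simulate a three-country adolescent cohort
#'
#' Generates participant records with the statistical structure the analysis
#' assumes: a per-country random intercept, demographic covariates, a
#' lognormal resting RMSSD (calibrated so raw RMSSD has mean ~43 ms and SD
#' ~13 ms, matching the adolescent norm reference), a configurable linear
#' effect of log-RMSSD on the latent outcome (default 0, the null
#' structure), ordinal item responses driven by latent traits through
#' proportional-odds cutpoints shared within instrument, and binomial task
#' choice counts.
#'
#' The continuous column `outcome` is generated exactly as
#' `intercept + u_country + beta_logrmssd * log_rmssd + covariate effects +
#' N(0, residual_sd)` and is the target for parameter-recovery and
#' type-I-error simulations. Each instrument's latent trait adds the same
#' systematic part (standardized) to unit logistic-scale noise, so the
#' scored totals inherit the configured country structure and (null or
#' non-null) HRV effect.
#'
#' @param n_per_country participants per country (3 countries; >= 2 each).
#' @param beta_logrmssd effect of log-RMSSD on the latent outcome, in
#'   outcome units per log(ms) (default 0).
#' @param country_intercept_sd SD of the country random intercept, outcome
#'   units (default 1).
#' @param residual_sd residual SD of the latent outcome (> 0).
#' @param intercept grand intercept of the latent outcome.
#' @param covariate_effects named numeric vector of slopes on `age` and/or
#'   `bmi` (default none).
#' @param item_thresholds list of proportional-odds cutpoints per instrument
#'   (`mmapp`, `ders`, `dbis`); must be strictly increasing.
#' @param trait_signal scale applied to the standardized systematic part
#'   when generating instrument latent traits (default 1).
#' @param rmssd_mean,rmssd_sd target mean and SD of raw RMSSD in ms.
#' @param seed integer seed (optional).
#' @return A data frame with one row per participant: identifiers,
#'   `country`, covariates, `device`, `rmssd`, `log_rmssd`, the continuous
#'   `outcome`, all item columns, task counts and the seven scored outcome
#'   columns. The generating parameters are attached as `attr(x, "truth")`.
#' @export
simulate_cohort <- function(n_per_country = 100,
                            beta_logrmssd = 0,
                            country_intercept_sd = 1,
                            residual_sd = 5,
                            intercept = 25,
                            covariate_effects = NULL,
                            item_thresholds = default_item_thresholds(),
                            trait_signal = 1,
                            rmssd_mean = 43, rmssd_sd = 13,
                            seed = NULL) {
  if (n_per_country < 2) stop("n_per_country must be >= 2")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  for (th in item_thresholds) {
    if (any(diff(th) <= 0)) stop("item thresholds must be strictly increasing")
  }
  if (!is.null(seed)) set.seed(seed)

  countries <- c("Colombia", "Nepal", "South_Africa")
  n <- 3L * n_per_country
  country <- factor(rep(countries, each = n_per_country), levels = countries)
  u <- stats::rnorm(3, 0, country_intercept_sd)
  names(u) <- countries

  age <- stats::runif(n, 13, 15)
  gender <- factor(
    sample(c("female", "male", "nonbinary"), n, replace = TRUE,
           prob = c(0.55, 0.44, 0.01)),
    levels = c("female", "male", "nonbinary")
  )
  height <- stats::rnorm(n, c(1.60, 1.56, 1.64)[as.integer(country)], 0.08)
  weight <- stats::rnorm(n, c(52, 47, 56)[as.integer(country)], 9)
  weight <- pmax(weight, 25)
  bmi <- weight / height^2
  # ECG chest straps everywhere in Colombia, mostly ear PPG elsewhere
  p_ecg <- c(1, 0.35, 0.22)[as.integer(country)]
  device <- factor(ifelse(stats::runif(n) < p_ecg, "ECG_chest", "PPG_ear"),
                   levels = c("ECG_chest", "PPG_ear"))

  # lognormal RMSSD with the requested raw-scale moments
  sigma2 <- log(1 + (rmssd_sd / rmssd_mean)^2)
  mu <- log(rmssd_mean) - sigma2 / 2
  log_rmssd <- stats::rnorm(n, mu, sqrt(sigma2))
  rmssd <- exp(log_rmssd)

  cov_eff <- numeric(n)
  if (!is.null(covariate_effects)) {
    for (nm in names(covariate_effects)) {
      cov_eff <- cov_eff + covariate_effects[[nm]] * get(nm)
    }
  }
  systematic <- u[as.integer(country)] + beta_logrmssd * log_rmssd + cov_eff
  outcome <- intercept + systematic + stats::rnorm(n, 0, residual_sd)

  # systematic part on the latent logistic trait scale: dividing by the
  # outcome residual SD preserves the signal-to-noise ratio of `outcome`
  sys_std <- (systematic - mean(systematic)) / residual_sd
  roster <- mh_item_roster()
  out <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    country = country, age = age, gender = gender, height = height,
    weight = weight, bmi = bmi, device = device,
    rmssd = rmssd, log_rmssd = log_rmssd, outcome = outcome,
    stringsAsFactors = FALSE
  )
  for (instr in c("mmapp", "ders", "dbis")) {
    theta <- trait_signal * sys_std + stats::rnorm(n)
    items <- draw_ordinal_items(theta, length(roster[[instr]]),
                                item_thresholds[[instr]])
    colnames(items) <- roster[[instr]]
    out <- cbind(out, as.data.frame(items))
  }

  # task choice counts: binomial, linked to a latent self-regulation trait
  theta_task <- trait_signal * sys_std + stats::rnorm(n)
  n_nogo <- 40L; n_go <- 80L
  fa <- stats::rbinom(n, n_nogo, stats::plogis(-1.1 + 0.3 * theta_task))
  hits <- stats::rbinom(n, n_go, 0.95)
  out$egng_false_alarms <- fa
  out$egng_responses <- fa + hits
  out$false_alarm_pct <- 100 * fa / pmax(out$egng_responses, 1)
  imm <- stats::rbinom(n, 30L, stats::plogis(-0.3 + 0.3 * theta_task))
  out$ddt_immediate <- imm
  out$ddt_responded <- 30L
  out$immediate_reward_pct <- 100 * imm / 30

  sc <- score_cohort(out)
  out$ders <- sc$ders
  out$mmapp_gad7 <- sc$mmapp_gad7
  out$mmapp_phqa <- sc$mmapp_phqa
  out$mmapp_total <- sc$mmapp_total
  out$dbis <- sc$dbis

  attr(out, "truth") <- list(
    beta_logrmssd = beta_logrmssd, intercept = intercept,
    country_intercepts = u, residual_sd = residual_sd,
    country_intercept_sd = country_intercept_sd,
    covariate_effects = covariate_effects
  )
  out
}

#' Default proportional-odds cutpoints per instrument
#'
#' Cutpoints on the latent logistic scale chosen so that, at a standard
#' normal trait, item and total score means sit in the range reported for
#' adolescent community samples (MMAPP totals in the low 20s, DERS totals in
#' the mid 20s, DBIS totals around 5).
#'
#' @return Named list of increasing cutpoint vectors (`mmapp`, `ders`,
#'   `dbis`).
#' @export
default_item_thresholds <- function() {
  list(
    mmapp = c(-0.5, 1.0, 2.2),
    ders = c(-1.2, -0.2, 0.8, 1.8),
    dbis = c(0.2, 1.5, 2.8)
  )
}

# Draw ordinal responses from a cumulative-logit (proportional-odds) model:
# P(Y <= k) = plogis(c_k - theta), categories 0..K.
draw_ordinal_items <- function(theta, n_items, cutpoints) {
  n <- length(theta)
  out <- matrix(0L, n, n_items)
  for (j in seq_len(n_items)) {
    u <- stats::runif(n)
    cum <- vapply(cutpoints, function(ck) stats::plogis(ck - theta),
                  numeric(n))
    out[, j] <- rowSums(u > cum)
  }
  out
}

#' Impose missingness on a cohort table
#'
#' Deletes cells (sets them to `NA`) under a chosen mechanism: MCAR deletes
#' uniformly at the given rate; MAR deletes with probability depending on an
#' observed auxiliary variable (default `age`) through a logistic model whose
#' intercept is calibrated so the expected overall rate matches `rate`. The
#' deleted cells are recorded, with their original values, in
#' `attr(x, "missing_cells")` as ground truth for imputation tests.
#'
#' @param data a cohort data frame.
#' @param rate target proportion of missing cells in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param vars columns to target (default: all item columns plus `height`
#'   and `weight`).
#' @param auxiliary fully observed numeric column driving MAR missingness.
#' @param mar_strength slope of the MAR logistic model on the standardized
#'   auxiliary (default 1).
#' @param seed integer seed (optional).
#' @return The table with `NA`s inserted and attribute `missing_cells`
#'   (data frame: `row`, `col`, `value`).
#' @export
impose_missingness <- function(data, rate, mechanism = c("MCAR", "MAR"),
                               vars = NULL, auxiliary = "age",
                               mar_strength = 1, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (is.null(vars)) {
    roster <- mh_item_roster()
    vars <- intersect(c(unlist(roster[c("mmapp", "ders", "dbis")]),
                        "height", "weight"), names(data))
  }
  if (!length(vars)) stop("no target columns found")
  if (rate == 0) {
    attr(data, "missing_cells") <-
      data.frame(row = integer(0), col = character(0), value = numeric(0))
    return(data)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  p_row <- if (mechanism == "MCAR") {
    rep(rate, n)
  } else {
    z <- as.numeric(scale(data[[auxiliary]]))
    # calibrate the intercept so mean(plogis(a + b z)) = rate
    a <- stats::uniroot(function(a) mean(stats::plogis(a + mar_strength * z)) - rate,
                        c(-20, 20))$root
    stats::plogis(a + mar_strength * z)
  }
  cells <- list()
  for (v in vars) {
    hit <- which(stats::runif(n) < p_row)
    if (length(hit)) {
      cells[[v]] <- data.frame(row = hit, col = v,
                               value = as.numeric(data[[v]][hit]))
      data[[v]][hit] <- NA
    }
  }
  attr(data, "missing_cells") <- if (length(cells)) {
    do.call(rbind, c(cells, list(make.row.names = FALSE)))
  } else {
    data.frame(row = integer(0), col = character(0), value = numeric(0))
  }
  data
}

#' Simulate an emotional go/no-go trial log
#'
#' Four experimental blocks of 20 go + 10 no-go trials preceded by 20
#' practice trials, with response probabilities set by hit and false-alarm
#' rates.
#'
#' @param p_hit probability of responding on a go trial.
#' @param p_fa probability of responding on a no-go trial.
#' @param participant_id identifier column value.
#' @param seed integer seed (optional).
#' @return Trial-per-row data frame with columns `participant_id`, `block`,
#'   `trial_type`, `response`, `practice`.
#' @export
simulate_egng_log <- function(p_hit = 0.95, p_fa = 0.15,
                              participant_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  practice <- data.frame(
    participant_id = participant_id, block = 0L,
    trial_type = sample(rep(c("go", "nogo"), c(13, 7))),
    practice = TRUE
  )
  blocks <- do.call(rbind, lapply(1:4, function(b) {
    data.frame(participant_id = participant_id, block = b,
               trial_type = sample(rep(c("go", "nogo"), c(20, 10))),
               practice = FALSE)
  }))
  log <- rbind(practice, blocks)
  p <- ifelse(log$trial_type == "go", p_hit, p_fa)
  log$response <- stats::runif(nrow(log)) < p
  log[, c("participant_id", "block", "trial_type", "response", "practice")]
}

#' Simulate a delay discounting trial log
#'
#' 30 binary choices between an immediate and a delayed reward.
#'
#' @param p_immediate probability of choosing the immediate option.
#' @param p_respond probability a trial is responded to at all.
#' @param participant_id identifier column value.
#' @param seed integer seed (optional).
#' @return Trial-per-row data frame with columns `participant_id`, `trial`,
#'   `choice` (`"immediate"`, `"delayed"` or `NA`).
#' @export
simulate_ddt_log <- function(p_immediate = 0.4, p_respond = 1,
                             participant_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 30L
  choice <- ifelse(stats::runif(n) < p_immediate, "immediate", "delayed")
  choice[stats::runif(n) >= p_respond] <- NA
  data.frame(participant_id = participant_id, trial = seq_len(n),
             choice = choice, stringsAsFactors = FALSE)
}
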