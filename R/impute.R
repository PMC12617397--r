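#' Screen missingness against auxiliary variables
#'
#' For each variable with missing cells, computes the point-biserial
#' correlation between its missingness indicator and each numeric auxiliary
#' variable, flagging correlations at or above `r_flag` (a conventional
#' screen for departures from MCAR).
#'
#' @param data the incomplete table.
#' @param vars variables to screen (default: all with missing cells).
#' @param auxiliaries numeric, fully observed columns (default: all such).
#' @param r_flag flag threshold on `|r|` (default 0.1).
#' @return Data frame with columns `variable`, `auxiliary`, `r`, `flagged`;
#'   `r` is `NA` when the missingness indicator is constant. Zero rows when
#'   nothing is missing.
#' @export
missingness_screen <- function(data, vars = NULL, auxiliaries = NULL,
                               r_flag = 0.1) {
  if (is.null(vars)) vars <- names(data)[vapply(data, anyNA, logical(1))]
  if (is.null(auxiliaries)) {
    auxiliaries <- names(data)[vapply(data, function(x)
      is.numeric(x) && !anyNA(x), logical(1))]
  }
  out <- expand.grid(variable = vars, auxiliary = auxiliaries,
                     stringsAsFactors = FALSE)
  if (!nrow(out)) {
    return(data.frame(variable = character(0), auxiliary = character(0),
                      r = numeric(0), flagged = logical(0)))
  }
  out$r <- mapply(function(v, a) {
    ind <- as.numeric(is.na(data[[v]]))
    if (stats::sd(ind) == 0) return(NA_real_)
    stats::cor(ind, data[[a]])
  }, out$variable, out$auxiliary)
  out$flagged <- !is.na(out$r) & abs(out$r) >= r_flag
  out
}

# REML fit of y = X beta + u[g] + e with a single random intercept.
# Profiles the variance ratio lambda = tau2/sigma2; O(n p^2) per evaluation.
ranint_reml <- function(y, X, g) {
  gi <- as.integer(g)
  ng <- tabulate(gi)
  n <- length(y)
  p <- ncol(X)
  vinv <- function(M, lam) {
    w <- lam / (1 + ng * lam)
    gs <- rowsum(M, gi, reorder = TRUE)
    M - w[gi] * gs[gi, , drop = FALSE]
  }
  guard <- function(A) {  # numerical ridge against near-collinear designs
    diag(A) <- diag(A) + 1e-10 * mean(diag(A))
    A
  }
  crit <- function(loglam) {
    lam <- exp(loglam)
    ViX <- vinv(X, lam)
    XtViX <- guard(crossprod(X, ViX))
    beta <- solve(XtViX, crossprod(ViX, y))
    r <- y - X %*% beta
    quad <- sum(r * vinv(r, lam))
    s2 <- quad / (n - p)
    (n - p) * log(s2) + sum(log(1 + ng * lam)) +
      as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(crit, c(-14, 10))
  lam <- exp(opt$minimum)
  if (crit(-30) <= opt$objective) lam <- 0  # boundary: no cluster variance
  ViX <- vinv(X, lam)
  XtViX <- guard(crossprod(X, ViX))
  beta <- drop(solve(XtViX, crossprod(ViX, y)))
  r <- drop(y - X %*% beta)
  quad <- sum(r * vinv(matrix(r), lam))
  sigma2 <- quad / (n - p)
  tau2 <- lam * sigma2
  gm <- drop(rowsum(r, gi)) / ng
  blup <- if (tau2 > 0) (lam * ng / (1 + lam * ng)) * gm else rep(0, length(ng))
  cond_var <- if (tau2 > 0) 1 / (ng / sigma2 + 1 / tau2) else rep(0, length(ng))
  list(beta = beta, XtViX = XtViX, sigma2 = sigma2, tau2 = tau2,
       blup = blup, cond_var = cond_var, quad = quad, df = n - p)
}

# Proper-imputation draw from a fitted random-intercept model, then imputed
# values for the missing design rows.
ranint_draw_impute <- function(fit, X_mis, g_mis) {
  s2_draw <- fit$quad / stats::rchisq(1, fit$df)
  Vb <- s2_draw * solve(fit$XtViX)
  beta_draw <- fit$beta + drop(chol(Vb) %*% stats::rnorm(length(fit$beta)))
  u_draw <- fit$blup + stats::rnorm(length(fit$blup), 0, sqrt(fit$cond_var))
  drop(X_mis %*% beta_draw) + u_draw[as.integer(g_mis)] +
    stats::rnorm(nrow(X_mis), 0, sqrt(s2_draw))
}

# predictive mean matching on a ridge-stabilized linear predictor;
# fallback used when a categorical conditional fit fails.
pmm_impute <- function(y_num, X, obs, mis, k = 5, ridge = 1e-5) {
  XtX <- crossprod(X[obs, , drop = FALSE])
  diag(XtX) <- diag(XtX) + ridge * mean(diag(XtX))
  beta <- solve(XtX, crossprod(X[obs, , drop = FALSE], y_num[obs]))
  lp <- drop(X %*% beta)
  vapply(mis, function(i) {
    d <- abs(lp[obs] - lp[i])
    donors <- obs[order(d)[seq_len(min(k, length(obs)))]]
    y_num[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

default_method_map <- function(data, vars) {
  roster <- mh_item_roster()
  items <- unlist(roster[c("mmapp", "ders", "dbis")], use.names = FALSE)
  vapply(vars, function(v) {
    if (v %in% items || is.ordered(data[[v]])) "proportional_odds"
    else if (is.factor(data[[v]]) || is.character(data[[v]])) "logistic"
    else "two_level_normal"
  }, character(1))
}

#' Multilevel multiple imputation by chained equations
#'
#' Fills missing cells by cycling type-specific conditional models:
#' proportional-odds regression for ordinal variables (imputed values drawn
#' from the fitted category probabilities, restricted to observed
#' categories), logistic/multinomial regression for nominal variables, and a
#' two-level normal model with a country random intercept for continuous
#' variables (parameters drawn from their sampling distribution, then
#' residuals). The cluster enters categorical conditionals as fixed
#' indicators and continuous conditionals as a random intercept. Variables
#' are visited in order of ascending missingness; `m` independent chains are
#' run from seed-derived substreams for `maxit` iterations each. BMI and
#' instrument totals are derived passively from the completed constituents.
#'
#' Proportional-odds fits that fail (empty categories, separation) fall back
#' to predictive mean matching on a ridge-stabilized linear predictor with
#' `pmm_k` donors; fallbacks are logged in the returned object.
#'
#' @param data the incomplete table (must contain `cluster_var`).
#' @param m number of imputed datasets (default 5, >= 2).
#' @param maxit chained-equation iterations per chain (default 10).
#' @param seed integer seed; drives all chains reproducibly.
#' @param methods named character vector mapping incomplete variables to
#'   `"proportional_odds"`, `"logistic"` or `"two_level_normal"`; defaults
#'   are inferred from column type (instrument items are ordinal).
#' @param cluster_var clustering factor (default `"country"`).
#' @param predictors predictor columns for every conditional model; default
#'   `log_rmssd`, `age`, `gender`, `height`, `weight` (those present).
#'   Instrument items additionally use the mean of the other items of their
#'   instrument (a rest score) as a predictor.
#' @param use_rest_scores logical; include the within-instrument rest score
#'   for item conditionals (default `TRUE`).
#' @param pmm_k donors for the predictive-mean-matching fallback.
#' @param ridge ridge stabilization constant for the fallback.
#' @return An object of class `imputed_datasets`: list with `datasets` (m
#'   completed data frames), `traces` (per chain/iteration/variable mean and
#'   SD of imputed values), `fallbacks` (log of fallback events), and the
#'   configuration (`m`, `maxit`, `seed`, `methods`).
#' @export
chained_impute <- function(data, m = 5, maxit = 10, seed = NULL,
                           methods = NULL, cluster_var = "country",
                           predictors = NULL, use_rest_scores = TRUE,
                           pmm_k = 5, ridge = 1e-5) {
  if (m < 2) stop("m must be >= 2")
  if (maxit < 1) stop("maxit must be >= 1")
  if (!cluster_var %in% names(data)) stop("cluster_var not found in data")
  if (anyNA(data[[cluster_var]])) stop("cluster variable must be complete")

  nmiss <- vapply(data, function(x) sum(is.na(x)), integer(1))
  vars <- names(nmiss)[nmiss > 0]
  if (is.null(methods)) {
    methods <- default_method_map(data, vars)
  } else {
    lacking <- setdiff(vars, names(methods))
    if (length(lacking)) stop("no method for: ", paste(lacking, collapse = ", "))
    methods <- methods[vars]
  }
  vars <- vars[order(nmiss[vars])]  # monotone ascending visit sequence

  if (is.null(predictors)) {
    predictors <- intersect(c("log_rmssd", "age", "gender", "height", "weight"),
                            names(data))
  }
  roster <- mh_item_roster()
  instr_of <- function(v) {
    for (instr in c("mmapp", "ders", "dbis")) {
      if (v %in% roster[[instr]]) return(instr)
    }
    NA_character_
  }

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, m)

  g <- factor(data[[cluster_var]])
  miss_idx <- lapply(data[vars], function(x) which(is.na(x)))
  names(miss_idx) <- vars
  traces <- list()
  fallbacks <- list()
  datasets <- vector("list", m)

  for (chain in seq_len(m)) {
    set.seed(chain_seeds[chain])
    cur <- data
    for (v in vars) {  # initial fill: draw from the observed margin
      mis <- miss_idx[[v]]
      obs_vals <- cur[[v]][-mis]
      cur[[v]][mis] <- sample(obs_vals, length(mis), replace = TRUE)
    }
    if (!length(vars)) {
      datasets[[chain]] <- passive_derive(cur)
      next
    }
    for (it in seq_len(maxit)) {
      for (v in vars) {
        mis <- miss_idx[[v]]
        obs <- setdiff(seq_len(nrow(cur)), mis)
        preds <- setdiff(predictors, v)
        dd <- droplevels(cur[, preds, drop = FALSE])
        instr <- instr_of(v)
        if (use_rest_scores && !is.na(instr)) {
          others <- setdiff(roster[[instr]], v)
          dd$rest_score <- rowMeans(cur[, others, drop = FALSE])
        }
        method <- methods[[v]]
        if (method == "two_level_normal") {
          X <- stats::model.matrix(~ ., data = dd)
          keep_col <- c(TRUE, apply(X[obs, -1, drop = FALSE], 2,
                                    function(cl) stats::var(cl) > 0))
          X <- X[, keep_col, drop = FALSE]
          fit <- ranint_reml(cur[[v]][obs], X[obs, , drop = FALSE], g[obs])
          cur[[v]][mis] <- ranint_draw_impute(fit, X[mis, , drop = FALSE],
                                              g[mis])
        } else if (method == "proportional_odds") {
          dd2 <- dd
          dd2[[cluster_var]] <- g
          yf <- factor(cur[[v]], ordered = TRUE)
          fit <- if (nlevels(droplevels(yf[obs])) < 2) NULL else
            tryCatch(
              suppressWarnings(MASS::polr(
                stats::reformulate(names(dd2), response = ".y"),
                data = cbind(.y = droplevels(yf), dd2)[obs, , drop = FALSE],
                Hess = FALSE)),
              error = function(e) NULL)
          drawn <- NULL
          if (!is.null(fit)) {
            pr <- tryCatch(
              stats::predict(fit, newdata = cbind(.y = yf, dd2)[mis, ,
                                                                drop = FALSE],
                             type = "probs"),
              error = function(e) NULL)
            if (!is.null(pr)) {
              pr <- matrix(pr, nrow = length(mis))
              lev <- as.numeric(fit$lev)
              drawn <- apply(pr, 1, function(p)
                lev[sample.int(length(lev), 1, prob = p)])
            }
          }
          if (is.null(drawn)) {
            X <- stats::model.matrix(~ ., data = dd2)
            drawn <- pmm_impute(as.numeric(cur[[v]]), X, obs, mis,
                                k = pmm_k, ridge = ridge)
            fallbacks[[length(fallbacks) + 1L]] <-
              data.frame(chain = chain, iteration = it, variable = v)
          }
          cur[[v]][mis] <- drawn
        } else { # logistic / multinomial
          dd2 <- dd
          dd2[[cluster_var]] <- g
          yf <- droplevels(factor(cur[[v]]))
          if (nlevels(yf) == 2) {
            fit <- suppressWarnings(stats::glm(
              stats::reformulate(names(dd2), response = ".y"),
              data = cbind(.y = yf, dd2)[obs, , drop = FALSE],
              family = stats::binomial()))
            p2 <- stats::predict(fit, newdata = dd2[mis, , drop = FALSE],
                                 type = "response")
            cur[[v]][mis] <- levels(yf)[1L + (stats::runif(length(mis)) < p2)]
          } else {
            fit <- nnet::multinom(
              stats::reformulate(names(dd2), response = ".y"),
              data = cbind(.y = yf, dd2)[obs, , drop = FALSE], trace = FALSE)
            pr <- stats::predict(fit, newdata = dd2[mis, , drop = FALSE],
                                 type = "probs")
            pr <- matrix(pr, nrow = length(mis))
            cur[[v]][mis] <- levels(yf)[apply(pr, 1, function(p)
              sample.int(length(p), 1, prob = p))]
          }
        }
        imp_vals <- suppressWarnings(as.numeric(cur[[v]][mis]))
        traces[[length(traces) + 1L]] <- data.frame(
          chain = chain, iteration = it, variable = v,
          mean = mean(imp_vals),
          sd = if (length(imp_vals) > 1) stats::sd(imp_vals) else 0
        )
        if (v %in% c("height", "weight") && "bmi" %in% names(cur)) {
          cur$bmi <- cur$weight / cur$height^2
        }
      }
    }
    datasets[[chain]] <- passive_derive(cur)
  }

  structure(list(
    datasets = datasets,
    traces = if (length(traces)) do.call(rbind, traces) else
      data.frame(chain = integer(0), iteration = integer(0),
                 variable = character(0), mean = numeric(0), sd = numeric(0)),
    fallbacks = if (length(fallbacks)) do.call(rbind, fallbacks) else
      data.frame(chain = integer(0), iteration = integer(0),
                 variable = character(0)),
    m = m, maxit = maxit, seed = seed, methods = methods
  ), class = "imputed_datasets")
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("<imputed_datasets> m = %d, maxit = %d, %d imputed variable(s)\n",
              x$m, x$maxit, length(x$methods)))
  invisible(x)
}

#' Passively derive BMI and instrument totals
#'
#' Recomputes derived variables from their completed constituents: BMI from
#' height (m) and weight (kg), and the instrument totals through the scoring
#' rules, whenever the corresponding source columns are present.
#'
#' @param data a completed table.
#' @return The table with `bmi`, `ders`, `mmapp_gad7`, `mmapp_phqa`,
#'   `mmapp_total`, `dbis` refreshed where derivable.
#' @export
passive_derive <- function(data) {
  if (all(c("height", "weight") %in% names(data))) {
    if (any(data$height <= 0, na.rm = TRUE)) {
      stop("nonpositive height; record invalid")
    }
    data$bmi <- data$weight / data$height^2
  }
  roster <- mh_item_roster()
  if (all(roster$ders %in% names(data))) data$ders <- score_ders(data)
  if (all(roster$mmapp %in% names(data))) {
    data$mmapp_gad7 <- score_gad7(data)
    data$mmapp_phqa <- score_phqa(data)
    data$mmapp_total <- score_mmapp_total(data)
  }
  if (all(roster$dbis %in% names(data))) data$dbis <- score_dbis(data)
  data
}
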