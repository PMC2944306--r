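#' Fit the covariate imputation model at one time point
#'
#' Ordinary least-squares regression of \eqn{X_t} on \eqn{X_{t-1}} (and
#' \eqn{E_{t-1}} when it varies in the fit sample), fitted on the observed
#' continuers: subjects observed at time `t` and event-free through
#' `t - 1`. Because continuers are by definition event-free, the
#' \eqn{E_{t-1}} column is constant (all zero) in every such sample and is
#' dropped with a note recorded on the fit. The fit carries the posterior
#' machinery for proper imputation under the standard noninformative prior:
#' residual variance drawn scaled inverse-chi-squared, coefficients normal
#' around the OLS solution.
#'
#' @param cohort an `attrition_cohort`.
#' @param t target time point, `2 <= t <= T` (no imputation at the first
#'   time point, where everyone is observed).
#' @return an `imputation_model` of type `"covariate"`: coefficients,
#'   residual variance (floored at 1e-12), residual degrees of freedom,
#'   unscaled coefficient covariance, fit sample size, dropped predictors.
#' @export
fit_covariate_model <- function(cohort, t) {
  fs <- imputation_fit_sample(cohort, t)
  obs <- observed_values(cohort)
  y <- obs$X[fs, t]
  Z <- cbind(`(Intercept)` = 1, X_prev = obs$X[fs, t - 1L],
             E_prev = obs$E[fs, t - 1L])
  dropped <- character(0)
  keep <- c(TRUE, apply(Z[, -1, drop = FALSE], 2, function(col) {
    stats::var(col) > 0
  }))
  if (!all(keep)) {
    dropped <- colnames(Z)[!keep]
    Z <- Z[, keep, drop = FALSE]
  }
  fit <- stats::lm.fit(Z, y)
  if (fit$rank < ncol(Z)) {
    stop(sprintf("degenerate covariate design at time %d", t))
  }
  df <- length(y) - ncol(Z)
  sigma2 <- max(sum(fit$residuals^2) / max(df, 1L), 1e-12)
  XtXinv <- tryCatch(chol2inv(chol(crossprod(Z))),
                     error = function(e) {
                       stop(sprintf("degenerate covariate design at time %d", t))
                     })
  structure(
    list(type = "covariate", t = t,
         coef = unname(fit$coefficients),
         predictors = colnames(Z), dropped = dropped,
         sigma2 = sigma2, df = df, XtXinv = XtXinv,
         n_fit = length(y), fallback = "none"),
    class = "imputation_model")
}

#' Fit the outcome imputation model at one time point
#'
#' Maximum-likelihood logistic regression of the event indicator \eqn{E_t}
#' on \eqn{X_t} (included linearly), fitted on the observed continuers at
#' time `t`. The coefficient covariance from the information matrix is
#' retained so chains can draw parameters from the asymptotic-normal
#' posterior approximation. Two fallbacks keep small samples workable: on
#' separation or non-convergence the fit is redone with two half-weight
#' pseudo-observations per class at the sample covariate mean (a mild
#' data-augmentation ridge); a single-class fit sample yields a model that
#' imputes Bernoulli draws at the class rate. The fallback used is recorded
#' in the `fallback` field.
#'
#' @inheritParams fit_covariate_model
#' @return an `imputation_model` of type `"outcome"`.
#' @export
fit_outcome_model <- function(cohort, t) {
  fs <- imputation_fit_sample(cohort, t)
  obs <- observed_values(cohort)
  y <- obs$E[fs, t]
  x <- obs$X[fs, t]
  if (length(unique(y)) < 2L) {
    return(structure(
      list(type = "outcome", t = t, coef = NULL, vcov = NULL,
           rate = mean(y), n_fit = length(y), fallback = "single_class"),
      class = "imputation_model"))
  }
  Z <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(Z, y, family = stats::binomial()))
  fallback <- "none"
  if (!fit$converged || max(abs(fit$coefficients)) > 15) {
    # separation: augment with half-weight pseudo-observations of each class
    Za <- rbind(Z, cbind(1, mean(x)), cbind(1, mean(x)))
    ya <- c(y, 0L, 1L)
    wa <- c(rep(1, length(y)), 0.5, 0.5)
    fit <- suppressWarnings(
      stats::glm.fit(Za, ya, weights = wa, family = stats::binomial()))
    Z <- Za
    fallback <- "ridge"
  }
  w <- fit$weights
  vcov <- chol2inv(chol(crossprod(Z * sqrt(w))))
  structure(
    list(type = "outcome", t = t, coef = unname(fit$coefficients),
         vcov = vcov, rate = NULL, n_fit = length(y), fallback = fallback),
    class = "imputation_model")
}

# Subjects eligible for fitting the time-t imputation models: observed at t
# and event-free (observed E all zero) through t-1.
imputation_fit_sample <- function(cohort, t) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  t <- as.integer(t)
  if (is.na(t) || t < 2L || t > cohort$T) {
    stop("imputation models exist only for time points 2..T; everyone is observed at t = 1")
  }
  obs <- observed_values(cohort)
  event_free <- rowSums(obs$E[, 1:(t - 1L), drop = FALSE]) == 0
  fs <- cohort$observed[, t] & !is.na(event_free) & event_free
  if (sum(fs) < 3L) {
    stop(sprintf("fewer than 3 subjects available to fit the time-%d imputation model", t))
  }
  fs
}

# Fit covariate + outcome models for every time point 2..T once; chains
# reuse them and only redraw parameters (fits use observed data only, so
# they are identical across chains).
fit_imputation_models <- function(cohort) {
  lapply(2:cohort$T, function(t) {
    list(cov = fit_covariate_model(cohort, t),
         out = fit_outcome_model(cohort, t))
  })
}

# Proper-imputation parameter draws.
draw_covariate_params <- function(fit) {
  if (fit$sigma2 <= 1e-12 || fit$df < 1L) {
    return(list(coef = fit$coef, sigma2 = fit$sigma2))
  }
  sigma2_star <- fit$df * fit$sigma2 / stats::rchisq(1, fit$df)
  coef_star <- fit$coef + sqrt(sigma2_star) *
    as.vector(t(chol(fit$XtXinv)) %*% stats::rnorm(length(fit$coef)))
  list(coef = coef_star, sigma2 = sigma2_star)
}

draw_outcome_params <- function(fit) {
  if (fit$fallback == "single_class") return(list(rate = fit$rate))
  coef_star <- fit$coef +
    as.vector(t(chol(fit$vcov)) %*% stats::rnorm(length(fit$coef)))
  list(coef = coef_star)
}

#' Run one sequential imputation chain
#'
#' Completes a monotone-missing cohort in time order. At each time point
#' `t = 2..T` the chain draws fresh model parameters from their posterior,
#' imputes \eqn{X_t} for subjects unobserved at `t` whose event history
#' (observed or imputed) through `t - 1` is all-zero, using their observed
#' or previously imputed \eqn{X_{t-1}}, then imputes
#' \eqn{E_t \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(b_0 + b_1 X_t))}.
#' Subjects with an earlier (observed or imputed) event receive no further
#' imputations; the final endpoint is recomputed over observed and imputed
#' indicators. Observed values are never altered.
#'
#' @param cohort an `attrition_cohort` with monotone missingness.
#' @param seed optional integer seed for this chain.
#' @param fits model fits from `fit_covariate_model()`/`fit_outcome_model()`
#'   per time point (computed internally when `NULL`); exposed so that the
#'   m chains of one analysis can share a single set of fits.
#' @return a `completed_cohort`: matrices `X`, `E` with all needed cells
#'   filled, logical matrix `imputed`, vector `endpoint`.
#' @export
impute_chain <- function(cohort, seed = NULL, fits = NULL) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  assert_monotone(cohort)
  if (is.null(fits)) fits <- fit_imputation_models(cohort)
  obs <- observed_values(cohort)
  n <- cohort$n; T <- cohort$T
  with_seed(seed, {
    Xc <- obs$X
    Ec <- obs$E
    Ec[is.na(Ec)] <- 0L     # placeholder in never-imputed cells (post-event)
    Xc[is.na(Xc)] <- NA_real_
    imputed <- matrix(FALSE, n, T)
    for (t in 2:T) {
      ft <- fits[[t - 1L]]
      cov_par <- draw_covariate_params(ft$cov)
      out_par <- draw_outcome_params(ft$out)
      need <- !cohort$observed[, t] &
        rowSums(Ec[, 1:(t - 1L), drop = FALSE]) == 0
      k <- sum(need)
      if (k) {
        zz <- cbind(1, Xc[need, t - 1L])
        if (length(cov_par$coef) == 3L) zz <- cbind(zz, 0)  # E_prev == 0
        mu <- as.vector(zz %*% cov_par$coef)
        Xc[need, t] <- mu + stats::rnorm(k, 0, sqrt(cov_par$sigma2))
        if (!is.null(out_par$rate)) {
          pr <- rep(out_par$rate, k)
        } else {
          pr <- stats::plogis(out_par$coef[1] + out_par$coef[2] * Xc[need, t])
        }
        Ec[need, t] <- stats::rbinom(k, 1L, pr)
        imputed[need, t] <- TRUE
      }
    }
    structure(
      list(X = Xc, E = Ec, imputed = imputed,
           endpoint = as.integer(rowSums(Ec) > 0),
           observed = cohort$observed, n = n, T = T),
      class = "completed_cohort")
  })
}

#' Occurrence proportion and its variance in a completed dataset
#'
#' The per-dataset analysis of the multiple-imputation pipeline: the mean
#' of the recomputed endpoint and its binomial variance
#' \eqn{\hat p (1 - \hat p)/n}.
#'
#' @param data a `completed_cohort` from [impute_chain()].
#' @return list with `estimate` and `variance`.
#' @export
proportion_estimate <- function(data) {
  stopifnot(inherits(data, "completed_cohort"))
  p <- mean(data$endpoint)
  list(estimate = p, variance = p * (1 - p) / data$n)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines m point estimates and within-imputation variances into the
#' pooled estimate \eqn{\bar Q}, within-variance \eqn{W}, between-variance
#' \eqn{B} (divisor m-1), total variance \eqn{T = W + (1 + 1/m) B}, and a
#' confidence interval on the t distribution with
#' \eqn{\nu = (m-1)\,(1 + W / ((1+1/m) B))^2} degrees of freedom. When
#' `B = 0` the interval uses the normal quantile (\eqn{\nu \to \infty}).
#' The Barnard-Rubin small-sample adjustment is available through
#' `df_rule = "barnard-rubin"` (requires `n_complete`, the complete-data
#' sample size).
#'
#' @param estimates numeric vector of per-imputation point estimates
#'   (length m >= 2).
#' @param variances matching vector of within-imputation variances.
#' @param conf_level confidence level, default 0.95.
#' @param df_rule `"rubin"` (default) or `"barnard-rubin"`.
#' @param n_complete complete-data sample size, only used by the
#'   Barnard-Rubin rule.
#' @return an `mi_pool`: `qbar`, `within`, `between`, `total_var`, `df`,
#'   `ci_lower`, `ci_upper`, `m`, plus the inputs.
#' @examples
#' rubin_pool(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.01, 5))
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95,
                       df_rule = c("rubin", "barnard-rubin"),
                       n_complete = NULL) {
  df_rule <- match.arg(df_rule)
  m <- length(estimates)
  if (m < 2L || length(variances) != m) {
    stop("rubin_pool needs matched estimate/variance vectors of length >= 2")
  }
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    if (df_rule == "barnard-rubin") {
      if (is.null(n_complete)) stop("barnard-rubin rule needs n_complete")
      nu_com <- n_complete - 1
      lambda <- (1 + 1 / m) * B / total
      nu_obs <- nu_com * (nu_com + 1) / (nu_com + 3) * (1 - lambda)
      df <- 1 / (1 / df + 1 / nu_obs)
    }
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
  }
  structure(
    list(qbar = qbar, within = W, between = B, total_var = total,
         df = df, m = m,
         ci_lower = qbar - q * sqrt(total),
         ci_upper = qbar + q * sqrt(total),
         conf_level = conf_level,
         estimates = estimates, variances = variances),
    class = "mi_pool")
}

#' @export
print.mi_pool <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over m = %d imputations: %.4f\n", x$m, x$qbar))
  cat(sprintf("  W = %.3g, B = %.3g, total var = %.3g, df = %.4g\n",
              x$within, x$between, x$total_var, x$df))
  cat(sprintf("  %d%% CI [%.4f, %.4f]\n", round(100 * x$conf_level),
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Multiple-imputation estimate of the cumulative occurrence rate
#'
#' Runs `m` independent sequential imputation chains ([impute_chain()],
#' sharing one set of model fits), computes the occurrence proportion and
#' its binomial variance in each completed dataset, and pools by Rubin's
#' rules. With no missing values every chain reproduces the observed data,
#' so the result is the sample proportion with
#' \eqn{se = \sqrt{\hat p (1 - \hat p)/n}} and a normal-quantile interval.
#'
#' @param cohort an `attrition_cohort` with monotone missingness.
#' @param m number of imputations (default 5).
#' @param seed optional integer seed; chain j runs under
#'   `child_seed(seed, j)`.
#' @param conf_level confidence level, default 0.95.
#' @param df_rule degrees-of-freedom rule, see [rubin_pool()].
#' @return an `occ_estimate` with `method = "MI"` and `df` the pooling
#'   degrees of freedom; the full `mi_pool` is attached as attribute
#'   `"pool"` and imputation-model fallbacks (separation handling) as
#'   attribute `"fallbacks"`.
#' @examples
#' sc <- default_scenarios()[["5"]]
#' ac <- apply_attrition(simulate_complete_cohort(sc, 2000, seed = 1), seed = 2)
#' mi_estimate(ac, m = 5, seed = 3)
#' @export
mi_estimate <- function(cohort, m = 5L, seed = NULL, conf_level = 0.95,
                        df_rule = c("rubin", "barnard-rubin")) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  df_rule <- match.arg(df_rule)
  assert_monotone(cohort)
  m <- as.integer(m)
  if (m < 2L) stop("m must be at least 2")
  if (all(cohort$observed)) {
    p <- mean(rowSums(observed_values(cohort)$E == 1L, na.rm = TRUE) > 0)
    se <- sqrt(p * (1 - p) / cohort$n)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    return(new_occ_estimate(p, se, p - z * se, p + z * se,
                            method = "MI", df = Inf, n = cohort$n,
                            conf_level = conf_level))
  }
  fits <- fit_imputation_models(cohort)
  fallbacks <- vapply(fits, function(f) f$out$fallback, "")
  Q <- U <- numeric(m)
  for (j in seq_len(m)) {
    chain_seed <- if (is.null(seed)) NULL else child_seed(seed, j)
    comp <- impute_chain(cohort, seed = chain_seed, fits = fits)
    pe <- proportion_estimate(comp)
    Q[j] <- pe$estimate; U[j] <- pe$variance
  }
  pool <- rubin_pool(Q, U, conf_level = conf_level, df_rule = df_rule,
                     n_complete = cohort$n)
  est <- new_occ_estimate(pool$qbar, sqrt(pool$total_var),
                          pool$ci_lower, pool$ci_upper,
                          method = "MI", df = pool$df, n = cohort$n,
                          conf_level = conf_level)
  attr(est, "pool") <- pool
  attr(est, "fallbacks") <- fallbacks
  est
}
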