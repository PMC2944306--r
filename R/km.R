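#' Build the discrete-time risk table of a cohort with attrition
#'
#' Converts subject trajectories into the per-time-point bookkeeping of the
#' product-limit estimator, treating drop-out as right-censoring. A subject
#' whose first observed event falls at time `t` counts as an event at `t`; a
#' subject who drops out after time `t` was still event-free and under
#' observation at `t`, so remains in the risk set at `t` and is censored in
#' `(t, t+1]`; event-free subjects observed through the last time point are
#' censored at end of study. Every subject contributes exactly one event or
#' one censoring.
#'
#' @param cohort an `attrition_cohort`.
#' @return a `risk_table`: a data.frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor` satisfying
#'   `n_risk[t+1] == n_risk[t] - n_event[t] - n_censor[t]`.
#' @export
build_risk_table <- function(cohort) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  if (cohort$n == 0L) stop("empty cohort")
  assert_monotone(cohort)
  T <- cohort$T
  E <- observed_values(cohort)$E
  fet <- rep(NA_integer_, cohort$n)
  for (t in T:1) fet[!is.na(E[, t]) & E[, t] == 1L] <- t
  evt <- !is.na(fet)
  time <- ifelse(evt, fet, cohort$last_observed)
  tab <- data.frame(
    time = seq_len(T),
    n_risk = vapply(seq_len(T), function(t) sum(time >= t), 0L),
    n_event = vapply(seq_len(T), function(t) sum(evt & time == t), 0L),
    n_censor = vapply(seq_len(T), function(t) sum(!evt & time == t), 0L))
  class(tab) <- c("risk_table", "data.frame")
  tab
}

#' Kaplan-Meier estimate of the cumulative occurrence rate
#'
#' Discrete-time product-limit estimator of the probability that the event
#' occurs by the end of follow-up:
#' \deqn{\hat P(E) = 1 - S(T), \qquad S(T) = \prod_{t \le T} (1 - d_t/n_t),}
#' with Greenwood's variance
#' \eqn{\widehat{var}[S(T)] = S(T)^2 \sum_t d_t / (n_t (n_t - d_t))}.
#' The default confidence interval is the plain symmetric interval
#' `estimate +/- z * se`; `conf_type = "loglog"` instead transforms the
#' survival scale by \eqn{\log(-\log S)}, which keeps the interval inside
#' `[0, 1]`.
#'
#' @param table a `risk_table` from [build_risk_table()].
#' @param conf_type `"plain"` (default) or `"loglog"`.
#' @param conf_level confidence level, default 0.95.
#' @return an `occ_estimate`: list with `estimate`, `se`, `ci_lower`,
#'   `ci_upper` (unclipped; `ci_lower_clipped`/`ci_upper_clipped` restrict
#'   to `[0, 1]`), `method = "KM"`, `df = NA`, `n`.
#' @examples
#' sc <- default_scenarios()[["1"]]
#' ac <- apply_attrition(simulate_complete_cohort(sc, 2000, seed = 1), seed = 2)
#' km_cumulative_rate(build_risk_table(ac))
#' @export
km_cumulative_rate <- function(table, conf_type = c("plain", "loglog"),
                               conf_level = 0.95) {
  conf_type <- match.arg(conf_type)
  stopifnot(inherits(table, "risk_table"))
  if (table$n_risk[1] == 0L) stop("empty risk table")
  S <- 1
  gsum <- 0  # Greenwood sum; terms with d_t = 0 vanish
  for (t in seq_len(nrow(table))) {
    nt <- table$n_risk[t]; dt <- table$n_event[t]
    if (nt > 0L && dt > 0L) {
      S <- S * (1 - dt / nt)
      if (nt > dt) gsum <- gsum + dt / (nt * (nt - dt))
      # nt == dt drives S to 0; the variance of a point mass is 0
    }
  }
  se <- S * sqrt(gsum)
  est <- 1 - S
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain" || S <= 0 || S >= 1) {
    ci <- c(est - z * se, est + z * se)
  } else {
    # CI on log(-log S), mapped back: S^exp(-+ z * se(loglog))
    se_ll <- sqrt(gsum) / abs(log(S))
    s_ci <- S^exp(c(z, -z) * se_ll)
    ci <- 1 - rev(s_ci)
    ci <- sort(ci)
  }
  new_occ_estimate(est, se, ci[1], ci[2], method = "KM", df = NA_real_,
                   n = table$n_risk[1], conf_type = conf_type,
                   conf_level = conf_level)
}

#' One-call Kaplan-Meier estimate from a cohort
#'
#' Convenience wrapper: [build_risk_table()] then [km_cumulative_rate()].
#'
#' @inheritParams build_risk_table
#' @inheritParams km_cumulative_rate
#' @return an `occ_estimate`.
#' @export
km_estimate <- function(cohort, conf_type = c("plain", "loglog"),
                        conf_level = 0.95) {
  km_cumulative_rate(build_risk_table(cohort),
                     conf_type = match.arg(conf_type),
                     conf_level = conf_level)
}

new_occ_estimate <- function(estimate, se, ci_lower, ci_upper, method, df, n,
                             conf_type = "plain", conf_level = 0.95) {
  structure(
    list(estimate = estimate, se = se,
         ci_lower = ci_lower, ci_upper = ci_upper,
         ci_lower_clipped = max(0, ci_lower),
         ci_upper_clipped = min(1, ci_upper),
         method = method, df = df, n = n,
         conf_type = conf_type, conf_level = conf_level),
    class = "occ_estimate")
}

#' @export
print.occ_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of P(E): %.3f (se %.4f, %d%% CI [%.3f, %.3f])\n",
              x$method, x$estimate, x$se, round(100 * x$conf_level),
              x$ci_lower, x$ci_upper))
  if (is.finite(x$df)) cat(sprintf("  df = %.1f\n", x$df))
  invisible(x)
}

#' @export
as.data.frame.occ_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, df = x$df,
             n = x$n, stringsAsFactors = FALSE)
}
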