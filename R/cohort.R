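#' Simulate a complete cohort (no missingness)
#'
#' Draws `n` subjects through `spec$T` discrete time points: the Gaussian
#' autoregressive covariate first, then at each time point a Bernoulli event
#' indicator with the category-specific probability (`p1` below the
#' threshold, `p2` at or above). Only the first event matters downstream:
#' `first_event_time` is the earliest time point with an event and the final
#' endpoint is its indicator. Event indicators after the first event are
#' retained in `E` but are never read by any estimator.
#'
#' @param spec a [scenario_spec()].
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards. Identical seeds give bit-identical cohorts.
#' @return an object of class `complete_cohort`: matrices `X` (numeric,
#'   n x T), `E` (0/1), `category` (1 = C1, 2 = C2), vectors
#'   `first_event_time` (NA when no event) and `endpoint` (0/1), the
#'   resolved `threshold`, and the `spec`.
#' @examples
#' co <- simulate_complete_cohort(default_scenarios()[["1"]], 500, seed = 1)
#' mean(co$endpoint)
#' @export
simulate_complete_cohort <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  with_seed(seed, {
    T <- spec$T
    X <- matrix(0, n, T)
    X[, 1] <- stats::rnorm(n, spec$init_mean, sqrt(spec$init_var))
    for (t in 2:T) {
      X[, t] <- spec$alpha + spec$beta * X[, t - 1] +
        stats::rnorm(n, 0, sqrt(spec$sigma2))
    }
    thr <- if (spec$threshold_mode == "empirical") {
      stats::median(X[, 1])
    } else {
      spec$threshold
    }
    category <- matrix(ifelse(X < thr, 1L, 2L), n, T)
    E <- matrix(0L, n, T)
    for (t in 1:T) {
      p <- ifelse(category[, t] == 1L, spec$p1, spec$p2)
      E[, t] <- stats::rbinom(n, 1L, p)
    }
    fet <- rep(NA_integer_, n)
    for (t in T:1) fet[E[, t] == 1L] <- t
    structure(
      list(X = X, E = E, category = category,
           first_event_time = fet,
           endpoint = as.integer(!is.na(fet)),
           threshold = thr, spec = spec, n = n, T = T),
      class = "complete_cohort")
  })
}

#' @export
print.complete_cohort <- function(x, ...) {
  cat(sprintf("Complete cohort: %d subjects, %d time points, occurrence rate %.1f%%\n",
              x$n, x$T, 100 * mean(x$endpoint)))
  invisible(x)
}

#' Cumulative occurrence rate of the event in a cohort
#'
#' The fraction of subjects who experience the event at least once over
#' follow-up. Computed on a complete cohort this is the true rate a
#' simulation scenario targets.
#'
#' @param cohort a `complete_cohort` (or an `attrition_cohort` that still
#'   carries the complete endpoint).
#' @return a fraction in `[0, 1]`.
#' @export
true_occurrence_rate <- function(cohort) {
  stopifnot(inherits(cohort, "complete_cohort"))
  if (cohort$n == 0L) stop("empty cohort")
  if (anyNA(cohort$endpoint)) {
    stop("endpoint is incomplete; the true rate needs the complete cohort")
  }
  mean(cohort$endpoint)
}

#' Superimpose monotone attrition on a complete cohort
#'
#' After each of the first `T - 1` time points, every subject still observed
#' and event-free through that time draws a drop-out indicator
#' \eqn{D_{it} \sim} Bernoulli(`r1` or `r2`, by current category). A drop-out
#' after time `t` makes all later time points unobserved (monotone pattern);
#' everyone is observed at the first time point. Subjects whose event has
#' already occurred are not at risk of drop-out.
#'
#' @param cohort a `complete_cohort`.
#' @param spec the [scenario_spec()] supplying `r1`, `r2` (defaults to the
#'   spec the cohort was simulated from).
#' @param seed optional integer seed.
#' @return an object of class `attrition_cohort`: all complete-cohort
#'   fields plus `D` (n x (T-1) drop-out indicators), `observed` (n x T
#'   logical mask) and `last_observed`. Estimators only ever read values
#'   where `observed` is `TRUE`.
#' @examples
#' sc <- default_scenarios()[["5"]]
#' ac <- apply_attrition(simulate_complete_cohort(sc, 1000, seed = 1), seed = 2)
#' total_dropout_rate(ac)
#' @export
apply_attrition <- function(cohort, spec = cohort$spec, seed = NULL) {
  stopifnot(inherits(cohort, "complete_cohort"), inherits(spec, "scenario_spec"))
  with_seed(seed, {
    n <- cohort$n; T <- cohort$T
    observed <- matrix(TRUE, n, T)
    D <- matrix(0L, n, T - 1L)
    fet <- cohort$first_event_time
    for (t in 1:(T - 1L)) {
      at_risk <- observed[, t] & (is.na(fet) | fet > t)
      r <- ifelse(cohort$category[, t] == 1L, spec$r1, spec$r2)
      D[, t] <- as.integer(stats::rbinom(n, 1L, r) == 1L & at_risk)
      if (any(D[, t] == 1L)) observed[D[, t] == 1L, (t + 1L):T] <- FALSE
    }
    out <- cohort
    out$D <- D
    out$observed <- observed
    out$last_observed <- as.integer(rowSums(observed))
    class(out) <- c("attrition_cohort", "complete_cohort")
    out
  })
}

#' @export
print.attrition_cohort <- function(x, ...) {
  cat(sprintf("Cohort with attrition: %d subjects, %d time points, %.1f%% dropped out\n",
              x$n, x$T, 100 * mean(rowSums(x$D) > 0)))
  invisible(x)
}

#' Total drop-out rate at the end of follow-up
#'
#' Fraction of subjects with any drop-out indicator set, i.e. the cumulative
#' attrition over the whole follow-up.
#'
#' @param cohort an `attrition_cohort`.
#' @return a fraction in `[0, 1]`.
#' @export
total_dropout_rate <- function(cohort) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  if (cohort$n == 0L) stop("empty cohort")
  mean(rowSums(cohort$D) > 0)
}

#' Draw an analysis sample from a cohort
#'
#' Uniform sampling of `m` subjects without replacement; every per-subject
#' field is carried over intact.
#'
#' @param cohort an `attrition_cohort` (or `complete_cohort`).
#' @param m sample size, at most the cohort size.
#' @param seed optional integer seed.
#' @return a cohort of the same class with `m` subjects.
#' @export
draw_sample <- function(cohort, m, seed = NULL) {
  stopifnot(inherits(cohort, "complete_cohort"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  if (m > cohort$n) stop("m exceeds the cohort size")
  idx <- with_seed(seed, sample.int(cohort$n, m))
  subset_cohort(cohort, idx)
}

# Row-subset every per-subject field of a cohort.
subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$X <- cohort$X[idx, , drop = FALSE]
  out$E <- cohort$E[idx, , drop = FALSE]
  out$category <- cohort$category[idx, , drop = FALSE]
  out$first_event_time <- cohort$first_event_time[idx]
  out$endpoint <- cohort$endpoint[idx]
  if (!is.null(cohort$D)) out$D <- cohort$D[idx, , drop = FALSE]
  if (!is.null(cohort$observed)) {
    out$observed <- cohort$observed[idx, , drop = FALSE]
    out$last_observed <- cohort$last_observed[idx]
  }
  out$n <- length(idx)
  out
}

# Masked views: X and E with NA wherever the observability mask is FALSE.
# All estimators go through this, so unobserved simulation values can never
# influence an estimate.
observed_values <- function(cohort) {
  stopifnot(inherits(cohort, "attrition_cohort"))
  X <- cohort$X; E <- cohort$E
  X[!cohort$observed] <- NA_real_
  E[!cohort$observed] <- NA_integer_
  list(X = X, E = E)
}

# Check the monotone observability pattern; returns offending subject ids.
check_monotone <- function(observed) {
  bad <- !observed[, 1]
  if (ncol(observed) > 1) {
    for (t in 1:(ncol(observed) - 1L)) {
      bad <- bad | (!observed[, t] & observed[, t + 1L])
    }
  }
  which(bad)
}

assert_monotone <- function(cohort) {
  bad <- check_monotone(cohort$observed)
  if (length(bad)) {
    stop("non-monotone observability pattern for subject(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  invisible(TRUE)
}
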