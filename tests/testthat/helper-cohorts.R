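# Shared fixtures: all cohorts are generated in code at test time.

# Minimal scenario factory with overridable parameters.
test_spec <- function(id = "test", p1 = 0.1, p2 = 0.1, r1 = 0.1, r2 = 0.1, ...) {
  scenario_spec(id, p1 = p1, p2 = p2, r1 = r1, r2 = r2, ...)
}

# Build an attrition cohort directly from explicit matrices, for
# hand-worked bookkeeping examples. `observed` defaults to all TRUE.
manual_cohort <- function(X, E, observed = NULL) {
  n <- nrow(X); T <- ncol(X)
  if (is.null(observed)) observed <- matrix(TRUE, n, T)
  fet <- rep(NA_integer_, n)
  for (t in T:1) fet[E[, t] == 1L] <- t
  D <- matrix(0L, n, T - 1L)
  for (t in seq_len(T - 1L)) {
    D[, t] <- as.integer(observed[, t] & !observed[, t + 1L] &
                           (is.na(fet) | fet > t))
  }
  structure(
    list(X = X, E = E,
         category = matrix(ifelse(X < 0.014, 1L, 2L), n, T),
         first_event_time = fet,
         endpoint = as.integer(!is.na(fet)),
         threshold = 0.014,
         spec = test_spec(), n = n, T = T,
         D = D, observed = observed,
         last_observed = as.integer(rowSums(observed))),
    class = c("attrition_cohort", "complete_cohort"))
}

# Per-subject event/censor encoding used against the survival-package
# oracle: first observed event time, else censoring at last observed time.
km_encoding <- function(cohort) {
  E <- cohort$E
  E[!cohort$observed] <- NA_integer_
  fet <- rep(NA_integer_, cohort$n)
  for (t in cohort$T:1) fet[!is.na(E[, t]) & E[, t] == 1L] <- t
  evt <- !is.na(fet)
  list(time = ifelse(evt, fet, cohort$last_observed), status = as.integer(evt))
}

# Closed forms for the p1 == p2, r1 == r2 special case, where the category
# split is irrelevant.
closed_form_occurrence <- function(p, T = 4) 1 - (1 - p)^T
closed_form_dropout <- function(p, r, T = 4) {
  sum(vapply(1:(T - 1), function(t) ((1 - p) * (1 - r))^(t - 1) * (1 - p) * r, 0))
}
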