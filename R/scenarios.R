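#' Define an attrition scenario
#'
#' A scenario bundles every generative parameter of one simulated cohort:
#' the autoregressive Gaussian covariate \eqn{X_{it}}, the category
#' threshold splitting subjects into low/high groups at each time point, the
#' per-category per-time-point event probabilities, and the per-category
#' drop-out probabilities applied after each of the first \eqn{T-1} time
#' points among event-free subjects.
#'
#' The covariate follows
#' \deqn{X_{i1} \sim N(\mu_0, \sigma_0^2), \quad
#'       X_{it} = \alpha + \beta X_{i,t-1} + \varepsilon_{it}, \quad
#'       \varepsilon_{it} \sim N(0, \sigma^2),}
#' with variances (not standard deviations) as parameters. At each time
#' point a subject belongs to category C1 when \eqn{X_{it} <} `threshold`
#' and to C2 otherwise (ties go to C2). Events are Bernoulli with
#' probability `p1` (C1) or `p2` (C2); drop-out after time \eqn{t < T} is
#' Bernoulli with probability `r1` or `r2` and can only happen to subjects
#' still event-free and under observation. Equal `r1` and `r2` make the
#' attrition completely at random (MCAR); unequal values make it depend on
#' the current observed covariate (MAR).
#'
#' @param scenario_id label for the scenario.
#' @param p1,p2 event probability per time point in categories C1 and C2
#'   (fractions in `[0, 1]`).
#' @param r1,r2 drop-out probability after each time point in C1 and C2.
#' @param T number of discrete follow-up time points (at least 2).
#' @param alpha,beta autoregression intercept and slope.
#' @param sigma2 innovation variance of the covariate process; may be 0 for
#'   degenerate (noise-free) test cohorts.
#' @param init_mean,init_var mean and variance of \eqn{X_{i1}}.
#' @param threshold category cut-point on \eqn{X_{it}}; the default 0.014 is
#'   the population median of \eqn{X_1} under the default covariate
#'   parameters, held fixed across time points.
#' @param threshold_mode `"fixed"` uses `threshold` as given; `"empirical"`
#'   replaces it with the realised median of \eqn{X_1} in each simulated
#'   cohort (a sensitivity option; scenario definitions then vary by seed).
#' @return an object of class `scenario_spec`.
#' @seealso [default_scenarios()] for the eight canonical MCAR/MAR
#'   scenarios, [simulate_complete_cohort()].
#' @examples
#' scenario_spec("mcar", p1 = 0.1, p2 = 0.6, r1 = 0.1, r2 = 0.1)
#' @export
scenario_spec <- function(scenario_id, p1, p2, r1, r2,
                          T = 4L, alpha = 1, beta = 1, sigma2 = 10,
                          init_mean = 0, init_var = 10,
                          threshold = 0.014,
                          threshold_mode = c("fixed", "empirical")) {
  threshold_mode <- match.arg(threshold_mode)
  probs <- c(p1 = p1, p2 = p2, r1 = r1, r2 = r2)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("event and drop-out probabilities must lie in [0, 1]")
  }
  T <- as.integer(T)
  if (is.na(T) || T < 2L) stop("T must be an integer >= 2")
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.finite(init_var) || init_var < 0) stop("init_var must be >= 0")
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(
    list(scenario_id = as.character(scenario_id),
         T = T, p1 = p1, p2 = p2, r1 = r1, r2 = r2,
         alpha = alpha, beta = beta, sigma2 = sigma2,
         init_mean = init_mean, init_var = init_var,
         threshold = threshold, threshold_mode = threshold_mode),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: T=%d, p=(%.0f%%, %.0f%%), r=(%.0f%%, %.0f%%), threshold=%g (%s)\n",
              x$scenario_id, x$T, 100 * x$p1, 100 * x$p2,
              100 * x$r1, 100 * x$r2, x$threshold, x$threshold_mode))
  invisible(x)
}

#' The eight canonical attrition scenarios
#'
#' Returns the eight scenarios of the reference simulation design: a common
#' covariate process (drift 1, slope 1, innovation variance 10, threshold
#' 0.014) crossed with category-specific event probabilities of 10/30/60%
#' and drop-out probabilities of 10/60%. Scenarios 1-3 are MCAR
#' (`r1 == r2`); scenarios 4-8 are MAR.
#'
#' @return a named list of [scenario_spec()] objects, names `"1"` to `"8"`.
#' @examples
#' default_scenarios()[["5"]]
#' @export
default_scenarios <- function() {
  grid <- list(
    `1` = c(0.1, 0.1, 0.1, 0.1),
    `2` = c(0.1, 0.3, 0.1, 0.1),
    `3` = c(0.1, 0.6, 0.1, 0.1),
    `4` = c(0.1, 0.1, 0.1, 0.6),
    `5` = c(0.1, 0.3, 0.1, 0.6),
    `6` = c(0.1, 0.6, 0.1, 0.6),
    `7` = c(0.1, 0.3, 0.6, 0.1),
    `8` = c(0.1, 0.6, 0.6, 0.1))
  lapply(stats::setNames(names(grid), names(grid)), function(id) {
    v <- grid[[id]]
    scenario_spec(id, p1 = v[1], p2 = v[2], r1 = v[3], r2 = v[4])
  })
}

#' Read scenario definitions from a YAML or JSON file
#'
#' The file holds a list of records whose keys match the arguments of
#' [scenario_spec()]; unknown keys are rejected. A bundled file with the
#' eight canonical scenarios ships at
#' `system.file("extdata", "scenarios.yaml", package = "miattrition")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list of `scenario_spec` objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || length(raw) == 0) stop("scenario file is empty")
  known <- names(formals(scenario_spec))
  specs <- lapply(raw, function(rec) {
    bad <- setdiff(names(rec), known)
    if (length(bad)) {
      stop("unknown scenario keys: ", paste(bad, collapse = ", "))
    }
    do.call(scenario_spec, rec)
  })
  stats::setNames(specs, vapply(specs, `[[`, "", "scenario_id"))
}
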