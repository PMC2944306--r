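#' Specify a replication study design
#'
#' Bundles everything that defines one evaluation run: the scenarios, the
#' reference cohort size, the analysis sample size, the number of
#' replications, the number of imputations, and the root seed from which
#' every per-(scenario, replication, chain) stream is derived.
#'
#' @param scenarios named list of [scenario_spec()] objects.
#' @param cohort_size size of the reference cohort each scenario simulates
#'   (default 100 000).
#' @param sample_size subjects per analysis sample (default 2000; 500 for
#'   the small-sample variant).
#' @param replications number of replications per scenario (default 500).
#' @param m_imputations imputations per multiple-imputation analysis
#'   (default 5).
#' @param root_seed integer root seed.
#' @param sampling_mode `"fixed-cohort"` (default) resamples the same
#'   reference attrition cohort in every replication; `"fresh-cohort"`
#'   simulates a new cohort of `sample_size` subjects per replication.
#' @param conf_type Kaplan-Meier confidence-interval flavour, see
#'   [km_cumulative_rate()].
#' @param df_rule pooling degrees-of-freedom rule, see [rubin_pool()].
#' @return an `evaluation_design`.
#' @export
evaluation_design <- function(scenarios = default_scenarios(),
                              cohort_size = 100000L,
                              sample_size = 2000L,
                              replications = 500L,
                              m_imputations = 5L,
                              root_seed = 1L,
                              sampling_mode = c("fixed-cohort", "fresh-cohort"),
                              conf_type = c("plain", "loglog"),
                              df_rule = c("rubin", "barnard-rubin")) {
  sampling_mode <- match.arg(sampling_mode)
  if (replications < 1L) stop("replications must be >= 1")
  if (sampling_mode == "fixed-cohort" && sample_size > cohort_size) {
    stop("sample_size cannot exceed cohort_size in fixed-cohort mode")
  }
  structure(
    list(scenarios = scenarios,
         cohort_size = as.integer(cohort_size),
         sample_size = as.integer(sample_size),
         replications = as.integer(replications),
         m_imputations = as.integer(m_imputations),
         root_seed = as.integer(root_seed),
         sampling_mode = sampling_mode,
         conf_type = match.arg(conf_type),
         df_rule = match.arg(df_rule)),
    class = "evaluation_design")
}

# Stable integer key for a scenario id, so seed streams do not depend on
# list position.
scenario_key <- function(scenario_id) {
  codes <- utf8ToInt(as.character(scenario_id))
  as.integer(sum(codes * seq_along(codes)) %% 1000003L)
}

default_methods <- function(design) {
  list(
    KM = function(cohort, seed, design) {
      km_estimate(cohort, conf_type = design$conf_type)
    },
    MI = function(cohort, seed, design) {
      mi_estimate(cohort, m = design$m_imputations, seed = seed,
                  df_rule = design$df_rule)
    })
}

# Build the reference complete + attrition cohorts of one scenario under
# the design's seed streams.
scenario_cohorts <- function(spec, design) {
  key <- scenario_key(spec$scenario_id)
  complete <- simulate_complete_cohort(
    spec, design$cohort_size, seed = child_seed(design$root_seed, key, 0, 1))
  attrition <- apply_attrition(
    complete, spec, seed = child_seed(design$root_seed, key, 0, 2))
  list(complete = complete, attrition = attrition, key = key)
}

#' Run one replication of a scenario evaluation
#'
#' Draws the replication's analysis sample from the reference attrition
#' cohort (or simulates a fresh one in fresh-cohort mode) and applies every
#' estimation method to the identical sample. All randomness comes from
#' child seeds of `(root_seed, scenario, rep)`, so any replication is
#' reproducible in isolation and results do not depend on execution order.
#'
#' @param cohort the scenario's reference `attrition_cohort`.
#' @param design an [evaluation_design()].
#' @param rep replication index (1-based).
#' @param methods named list of estimator functions
#'   `function(cohort, seed, design) -> occ_estimate`; defaults to
#'   Kaplan-Meier and multiple imputation.
#' @return named list of `occ_estimate` objects, one per method.
#' @export
run_replication <- function(cohort, design, rep, methods = NULL) {
  stopifnot(inherits(design, "evaluation_design"))
  if (is.null(methods)) methods <- default_methods(design)
  key <- scenario_key(cohort$spec$scenario_id)
  smp <- if (design$sampling_mode == "fixed-cohort") {
    draw_sample(cohort, design$sample_size,
                seed = child_seed(design$root_seed, key, rep, 1))
  } else {
    fresh <- simulate_complete_cohort(
      cohort$spec, design$sample_size,
      seed = child_seed(design$root_seed, key, rep, 1))
    apply_attrition(fresh, cohort$spec,
                    seed = child_seed(design$root_seed, key, rep, 2))
  }
  out <- vector("list", length(methods))
  names(out) <- names(methods)
  for (i in seq_along(methods)) {
    out[[i]] <- tryCatch(
      methods[[i]](smp, child_seed(design$root_seed, key, rep, 2L + i),
                   design),
      error = function(e) {
        stop(sprintf("scenario %s, replication %d, method %s: %s",
                     cohort$spec$scenario_id, rep, names(methods)[i],
                     conditionMessage(e)))
      })
  }
  out
}

#' Evaluate one scenario over replications
#'
#' Simulates the scenario's reference cohorts, takes the true occurrence
#' rate from the complete cohort, runs every replication, and aggregates
#' per method: mean estimate, mean standard error, empirical SD of the
#' estimates, bias (mean estimate minus true rate, in percentage points)
#' and 95% confidence-interval coverage (percent of replications whose CI
#' contains the true rate).
#'
#' @param spec a [scenario_spec()].
#' @param design an [evaluation_design()].
#' @param methods see [run_replication()].
#' @return a `scenario_summary`: list with `summary` (one data.frame row
#'   per method, percent scale), `true_rate`, `dropout_rate`,
#'   `replications` (per-replication estimates, fraction scale), and the
#'   `spec`.
#' @export
evaluate_scenario <- function(spec, design, methods = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(design, "evaluation_design"))
  if (is.null(methods)) methods <- default_methods(design)
  ref <- scenario_cohorts(spec, design)
  true_rate <- true_occurrence_rate(ref$complete)
  dropout <- total_dropout_rate(ref$attrition)
  R <- design$replications
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    res <- run_replication(ref$attrition, design, r, methods = methods)
    reps[[r]] <- do.call(rbind, lapply(names(res), function(mth) {
      e <- res[[mth]]
      data.frame(rep = r, method = mth, estimate = e$estimate, se = e$se,
                 ci_lower = e$ci_lower, ci_upper = e$ci_upper,
                 stringsAsFactors = FALSE)
    }))
  }
  reps <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(names(methods), function(mth) {
    d <- reps[reps$method == mth, ]
    data.frame(
      scenario_id = spec$scenario_id, method = mth,
      true_rate = 100 * true_rate,
      mean_estimate = 100 * mean(d$estimate),
      mean_se = 100 * mean(d$se),
      empirical_sd = 100 * stats::sd(d$estimate),
      bias = 100 * (mean(d$estimate) - true_rate),
      coverage = 100 * mean(d$ci_lower <= true_rate & true_rate <= d$ci_upper),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(
    list(summary = summ, true_rate = true_rate, dropout_rate = dropout,
         replications = reps, spec = spec, design = design),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario %s: true rate %.1f%%, drop-out %.1f%%, %d replications\n",
              x$spec$scenario_id, 100 * x$true_rate, 100 * x$dropout_rate,
              x$design$replications))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Reproduce the scenario-parameter and performance tables
#'
#' Runs [evaluate_scenario()] for every scenario of the design and
#' assembles two reports: `table1` (scenario parameters with the simulated
#' total drop-out and true occurrence rates, percent scale) and `table2`
#' (per scenario and method: mean estimate, mean SE, bias, coverage). When
#' `out_dir` is given, writes `table1.csv`, `table2.csv` and a
#' `manifest.json` recording the design, seeds, package version and
#' empirical SDs, sufficient to re-run the command bit-identically.
#'
#' @param design an [evaluation_design()].
#' @param out_dir optional output directory (created if missing).
#' @param verbose print per-scenario progress (default TRUE).
#' @return list with data.frames `table1` and `table2` and the per-scenario
#'   `scenario_summary` objects, invisibly when `out_dir` is given.
#' @export
reproduce_tables <- function(design, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(design, "evaluation_design"))
  results <- vector("list", length(design$scenarios))
  names(results) <- names(design$scenarios)
  for (id in names(design$scenarios)) {
    if (verbose) message("evaluating scenario ", id, " ...")
    results[[id]] <- evaluate_scenario(design$scenarios[[id]], design)
  }
  table1 <- do.call(rbind, lapply(names(results), function(id) {
    sp <- design$scenarios[[id]]
    data.frame(scenario_id = id,
               p1 = 100 * sp$p1, p2 = 100 * sp$p2,
               r1 = 100 * sp$r1, r2 = 100 * sp$r2,
               dropout_rate = 100 * results[[id]]$dropout_rate,
               true_rate = 100 * results[[id]]$true_rate,
               stringsAsFactors = FALSE)
  }))
  table2 <- do.call(rbind, lapply(results, function(r) r$summary))
  rownames(table1) <- rownames(table2) <- NULL
  out <- list(table1 = table1, table2 = table2, results = results)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(table1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(table2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    manifest <- list(
      package = "miattrition",
      version = as.character(utils::packageVersion("miattrition")),
      r_version = R.version.string,
      design = list(
        scenario_ids = names(design$scenarios),
        cohort_size = design$cohort_size,
        sample_size = design$sample_size,
        replications = design$replications,
        m_imputations = design$m_imputations,
        root_seed = design$root_seed,
        sampling_mode = design$sampling_mode,
        conf_type = design$conf_type,
        df_rule = design$df_rule),
      empirical_sd = stats::setNames(
        lapply(results, function(r) {
          stats::setNames(as.list(r$summary$empirical_sd), r$summary$method)
        }), names(results)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
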