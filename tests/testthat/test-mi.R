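test_that("the covariate model recovers a noise-free autoregression exactly", {
  sp <- test_spec(sigma2 = 0, init_var = 10, r1 = 0.3, r2 = 0.3)
  ac <- apply_attrition(simulate_complete_cohort(sp, 400, seed = 1), sp, seed = 2)
  fit <- fit_covariate_model(ac, 2)
  expect_equal(fit$coef[1], 1, tolerance = 1e-6)
  expect_equal(fit$coef[2], 1, tolerance = 1e-6)
  expect_lte(fit$sigma2, 1e-10)  # floored residual variance
  expect_true("E_prev" %in% fit$dropped)
})

test_that("imputation models are refused at the first time point and on tiny fit samples", {
  sp <- default_scenarios()[["1"]]
  ac <- apply_attrition(simulate_complete_cohort(sp, 200, seed = 3), sp, seed = 4)
  expect_error(fit_covariate_model(ac, 1), "time points 2")
  expect_error(fit_outcome_model(ac, 5), "time points 2")
  tiny <- miattrition:::subset_cohort(ac, 1:2)
  expect_error(fit_covariate_model(tiny, 2), "fewer than 3")
})

test_that("the covariate model recovers the generative parameters on a large cohort", {
  sp <- default_scenarios()[["1"]]
  n <- 20000
  ac <- apply_attrition(simulate_complete_cohort(sp, n, seed = 5), sp, seed = 6)
  for (t in 2:4) {
    fit <- fit_covariate_model(ac, t)
    se_coef <- sqrt(diag(fit$XtXinv) * fit$sigma2)
    expect_lt(abs(fit$coef[1] - 1), 4 * se_coef[1])  # alpha = 1
    expect_lt(abs(fit$coef[2] - 1), 4 * se_coef[2])  # beta = 1
    se_s2 <- fit$sigma2 * sqrt(2 / fit$df)
    expect_lt(abs(fit$sigma2 - 10), 4 * se_s2)       # innovation variance = 10
  }
})

test_that("the outcome model finds no covariate effect when none exists", {
  sp <- test_spec(p1 = 0.5, p2 = 0.5, r1 = 0.2, r2 = 0.2)
  ac <- apply_attrition(simulate_complete_cohort(sp, 10000, seed = 7), sp, seed = 8)
  fit <- fit_outcome_model(ac, 2)
  expect_equal(fit$fallback, "none")
  expect_lt(abs(fit$coef[2]), 4 * sqrt(fit$vcov[2, 2]))
})

test_that("the fitted logistic orders the two categories and sits near their event rates", {
  # the true event model is a 10%/60% step in X; a logistic fit smooths the
  # step, so within-category mean fitted probabilities approach (not equal)
  # the category rates
  sp <- default_scenarios()[["3"]]
  ac <- apply_attrition(simulate_complete_cohort(sp, 50000, seed = 9), sp, seed = 10)
  for (t in 2:3) {
    fit <- fit_outcome_model(ac, t)
    fs <- miattrition:::imputation_fit_sample(ac, t)
    x <- miattrition:::observed_values(ac)$X[fs, t]
    p <- plogis(fit$coef[1] + fit$coef[2] * x)
    m1 <- mean(p[x < sp$threshold]); m2 <- mean(p[x >= sp$threshold])
    expect_gt(fit$coef[2], 0)
    expect_lt(m1, m2)
    expect_true(m1 > 0.05 && m1 < 0.3)
    expect_true(m2 > 0.4 && m2 < 0.7)
  }
})

test_that("a single-class fit sample falls back to the class rate instead of crashing", {
  sp <- test_spec(p1 = 0, p2 = 0, r1 = 0.3, r2 = 0.3)
  ac <- apply_attrition(simulate_complete_cohort(sp, 300, seed = 11), sp, seed = 12)
  fit <- fit_outcome_model(ac, 2)
  expect_equal(fit$fallback, "single_class")
  expect_equal(fit$rate, 0)
  est <- mi_estimate(ac, m = 3, seed = 13)
  expect_equal(est$estimate, 0)
})

test_that("imputation chains fill exactly the needed cells and never touch observed values", {
  sp <- default_scenarios()[["5"]]
  ac <- apply_attrition(simulate_complete_cohort(sp, 2000, seed = 21), sp, seed = 22)
  obs <- miattrition:::observed_values(ac)
  c1 <- impute_chain(ac, seed = 31)
  c2 <- impute_chain(ac, seed = 32)
  # observed values unchanged in both chains
  expect_equal(c1$X[ac$observed], obs$X[ac$observed])
  expect_equal(c2$X[ac$observed], obs$X[ac$observed])
  expect_equal(c1$E[ac$observed], obs$E[ac$observed])
  # different seeds change only imputed values
  expect_false(identical(c1$X[c1$imputed], c2$X[c2$imputed]))
  # imputation respects first-occurrence logic: nothing imputed after an
  # observed-or-imputed event
  for (ch in list(c1, c2)) {
    first_evt <- apply(ch$E == 1L, 1, function(z) {
      w <- which(z); if (length(w)) w[1] else 5L
    })
    later <- col(ch$imputed) > first_evt
    expect_false(any(ch$imputed & later))
  }
  # only unobserved cells are ever imputed
  expect_false(any(c1$imputed & ac$observed))
})

test_that("a chain on a fully observed cohort reproduces the input", {
  sp <- test_spec(r1 = 0, r2 = 0)
  ac <- apply_attrition(simulate_complete_cohort(sp, 300, seed = 41), sp, seed = 42)
  ch <- impute_chain(ac, seed = 43)
  expect_equal(ch$X, ac$X)
  expect_equal(ch$endpoint, ac$endpoint)
  expect_false(any(ch$imputed))
})

test_that("proportion_estimate matches its closed form", {
  mk <- function(endpoint) structure(list(endpoint = endpoint,
                                          n = length(endpoint)),
                                     class = "completed_cohort")
  expect_equal(proportion_estimate(mk(rep(1L, 10))),
               list(estimate = 1, variance = 0))
  pe <- proportion_estimate(mk(rep(c(1L, 0L), each = 1000)))
  expect_equal(pe$estimate, 0.5)
  expect_equal(pe$variance, 0.000125)
  pe2 <- proportion_estimate(mk(c(rep(1L, 1220), rep(0L, 780))))
  expect_equal(pe2$variance, 0.61 * 0.39 / 2000)
})

test_that("Rubin pooling reproduces hand-worked combining rules", {
  p <- rubin_pool(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.01, 5))
  expect_equal(p$qbar, 0.3)
  expect_equal(p$within, 0.01)
  expect_equal(p$between, 0.025)
  expect_equal(p$total_var, 0.04)
  expect_equal(p$df, 4 * (4 / 3)^2)
  expect_equal(p$ci_lower, 0.3 - qt(0.975, 64 / 9) * 0.2)

  # identical estimates: B = 0, total = W, normal quantile
  p0 <- rubin_pool(rep(0.5, 5), rep(0.02, 5))
  expect_equal(p0$between, 0)
  expect_equal(p0$total_var, 0.02)
  expect_equal(p0$df, Inf)
  expect_equal(p0$ci_upper, 0.5 + qnorm(0.975) * sqrt(0.02))

  expect_error(rubin_pool(0.5, 0.01), "length >= 2")

  # total variance never falls below the within-imputation variance
  set.seed(99)
  for (i in 1:20) {
    q <- runif(5); v <- runif(5, 0.001, 0.01)
    pp <- rubin_pool(q, v)
    expect_gte(pp$total_var, pp$within)
  }

  # Barnard-Rubin adjustment shrinks the degrees of freedom
  pbr <- rubin_pool(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.01, 5),
                    df_rule = "barnard-rubin", n_complete = 2000)
  expect_lt(pbr$df, p$df)
})

test_that("MI on a cohort without missingness collapses to the sample proportion", {
  sp <- test_spec(p1 = 0.2, p2 = 0.4, r1 = 0, r2 = 0)
  ac <- apply_attrition(simulate_complete_cohort(sp, 500, seed = 51), sp, seed = 52)
  est <- mi_estimate(ac, m = 5, seed = 53)
  p <- mean(ac$endpoint)
  expect_equal(est$estimate, p)
  expect_equal(est$se, sqrt(p * (1 - p) / 500))
  expect_equal(km_estimate(ac)$estimate, p)
})

test_that("estimates cannot leak unobserved simulation values", {
  sp <- default_scenarios()[["8"]]
  ac <- apply_attrition(simulate_complete_cohort(sp, 1500, seed = 61), sp, seed = 62)
  scrambled <- ac
  scrambled$X[!ac$observed] <- 999
  scrambled$E[!ac$observed] <- 1L
  expect_equal(km_estimate(scrambled)$estimate, km_estimate(ac)$estimate)
  expect_equal(km_estimate(scrambled)$se, km_estimate(ac)$se)
  e1 <- mi_estimate(ac, m = 3, seed = 63)
  e2 <- mi_estimate(scrambled, m = 3, seed = 63)
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e1$se, e2$se)
})

test_that("mi_estimate is deterministic given a seed", {
  sp <- default_scenarios()[["5"]]
  ac <- apply_attrition(simulate_complete_cohort(sp, 1000, seed = 71), sp, seed = 72)
  e1 <- mi_estimate(ac, seed = 73)
  e2 <- mi_estimate(ac, seed = 73)
  expect_identical(e1$estimate, e2$estimate)
  expect_identical(e1$se, e2$se)
  expect_identical(e1$df, e2$df)
})
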