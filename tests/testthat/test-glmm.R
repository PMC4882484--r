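# Mixed-effects fitting: degenerate reduction to plain logistic regression,
# marginal-likelihood accuracy, Wald inference and the parametric bootstrap.

test_that("dropping the random term reduces to ordinary logistic regression", {
  tr <- simulate_group(respondent_model_us(sigma_id = 0), 30, "US", seed = 2)
  f <- fit_logistic_mixed(tr, "pooled", random_participant = FALSE)
  coded <- code_predictors(tr$frequency, tr$amplitude, tr$spikiness)
  ref <- stats::glm(tr$response ~ coded$frequency + coded$amplitude +
                      coded$spikiness, family = stats::binomial())
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_identical(f$n_parameters, 4L)
  expect_length(f$variance_components, 0)
})

test_that("reported log-likelihood matches brute-force integration", {
  m <- respondent_model(-0.3, 0.15, 0.02, 0.01, sigma_id = 1)
  tr <- simulate_group(m, 5, "TW", design = mini_design(), seed = 51)
  f <- fit_logistic_mixed(tr, "pooled", nagq = 25)
  X <- cbind(1, f$data$frequency, f$data$amplitude, f$data$spikiness)
  ll <- brute_force_loglik(f$coefficients,
                           unname(f$variance_components["sigma_participant_id"]),
                           X, f$data$response, f$data$participant_id)
  expect_lt(abs(f$log_likelihood - ll), 1e-4)
  expect_equal(f$deviance, -2 * f$log_likelihood)
})

test_that("fit results carry coherent inference fields", {
  tr <- simulate_group(respondent_model_us(), 25, "US", seed = 12)
  f <- fit_logistic_mixed(tr, "pooled")
  expect_true(f$converged)
  expect_identical(f$n_obs, 1800L)
  expect_identical(f$n_parameters, 5L)
  expect_true(all(f$ci_lower < f$coefficients & f$coefficients < f$ci_upper))
  expect_equal(unname(f$z_values),
               unname(f$coefficients / f$se_hessian))
  tab <- fit_table(f)
  expect_identical(tab$factor,
                   c("constant", "frequency", "amplitude", "spikiness"))
  expect_identical(unique(tab$se_type), "hessian")
})

test_that("separated responses raise a diagnostic error", {
  tr <- simulate_group(respondent_model_us(), 4, "US", seed = 5)
  tr$response <- 1L
  expect_error(fit_logistic_mixed(tr, "pooled"), "separat")
  expect_error(fit_logistic_mixed(tr[tr$participant_id == "US0001", ],
                                  "pooled"), "participants")
})

test_that("Wald intervals and tests follow the 1.96 formula", {
  ci <- wald_ci(0.394, 0.014)
  expect_equal(unname(ci[, "upper"]), 0.394 + 1.96 * 0.014)
  expect_equal(wald_ci(0, 1)[1, ], c(lower = -1.96, upper = 1.96))
  expect_error(wald_ci(1, 0), "se")
  wt <- wald_test(0, 1)
  expect_equal(wt$z, 0)
  expect_equal(wt$p, 1)
  expect_equal(wald_test(1.96, 1)$p, 0.05, tolerance = 1e-3)
  wt <- wald_test(0.394, 0.014)
  expect_equal(wt$z, 28.142857, tolerance = 1e-6)
  expect_lt(wt$p, 1e-10)
  expect_error(wald_test(1, -1), "se")
})

test_that("parametric bootstrap SEs are deterministic and near Hessian SEs", {
  tr <- simulate_group(respondent_model_us(), 25, "US",
                       design = mini_design(), seed = 14)
  f <- fit_logistic_mixed(tr, "pooled")
  f1 <- parametric_bootstrap_se(f, n_boot = 60, seed = 9)
  f2 <- parametric_bootstrap_se(f, n_boot = 60, seed = 9)
  expect_identical(f1$se_bootstrap, f2$se_bootstrap)
  ratio <- f1$se_bootstrap["frequency"] / f1$se_hessian["frequency"]
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
  expect_identical(unique(fit_table(f1)$se_type), "bootstrap")
  expect_error(parametric_bootstrap_se(f, n_boot = 10), "n_boot")
})

test_that("bootstrap SEs match the delta-method SEs for independent trials", {
  # slopes and random-intercept SD zero: the fit is plain logistic
  # regression and the information-matrix (delta-method) SEs are exact
  # asymptotically, so the parametric bootstrap must agree closely
  flat <- respondent_model(0, 0, 0, 0, sigma_id = 0)
  tr <- simulate_group(flat, 120, "US", seed = 33)
  f <- fit_logistic_mixed(tr, "pooled", random_participant = FALSE)
  f <- parametric_bootstrap_se(f, n_boot = 200, seed = 2)
  ratio <- f$se_bootstrap / f$se_hessian
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("Wald CIs cover generating slopes at nominal rates", {
  covered <- matrix(FALSE, nrow = 60, ncol = 3,
                    dimnames = list(NULL, c("frequency", "amplitude",
                                            "spikiness")))
  truth <- c(frequency = 0.394, amplitude = 0.089, spikiness = 0.014)
  for (r in seq_len(nrow(covered))) {
    tr <- simulate_group(respondent_model_us(), 20, "US", seed = 300 + r)
    f <- fit_logistic_mixed(tr, "pooled")
    covered[r, ] <- f$ci_lower[names(truth)] < truth &
      truth < f$ci_upper[names(truth)]
  }
  # stochastic bound: at least 85% empirical coverage per slope
  expect_true(all(colMeans(covered) >= 0.85))
})
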