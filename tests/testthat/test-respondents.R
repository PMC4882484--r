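# Generative respondent model: predictor coding, response probabilities,
# and the two-group trial simulator.

test_that("predictor coding scales amplitude by 100 by default", {
  expect_equal(code_predictors(4, 0.1, 0),
               data.frame(frequency = 4, amplitude = 10, spikiness = 0))
  expect_equal(code_predictors(9, 0.4, 30),
               data.frame(frequency = 9, amplitude = 40, spikiness = 30))
  expect_equal(code_predictors(4, 0.1, 0, coding = "identity"),
               data.frame(frequency = 4, amplitude = 0.1, spikiness = 0))
  expect_error(code_predictors(4, 0.1, 0, coding = "nope"))
})

test_that("response probabilities follow the inverse-logit linear predictor", {
  flat <- respondent_model(0, 0, 0, 0, sigma_id = 0)
  expect_equal(response_probability(flat, 6, 0.2, 1), 0.5)
  shifted <- respondent_model(-4.835, 0, 0, 0, sigma_id = 0)
  expect_equal(response_probability(shifted, 6, 0.2, 1), plogis(-4.835))
  # arithmetic oracle on the US reference coefficients, default coding
  p <- response_probability(respondent_model_us(), 9, 0.4, 30)
  expect_equal(p, plogis(-4.835 + 0.394 * 9 + 0.089 * 40 + 0.014 * 30))
  expect_equal(p, 0.9364935, tolerance = 1e-6)
  # delta slopes apply only to the US group
  comb <- respondent_model_combined()
  p_tw <- response_probability(comb, 6, 0.3, 1, group = "TW")
  p_us <- response_probability(comb, 6, 0.3, 1, group = "US")
  expect_equal(qlogis(p_us) - qlogis(p_tw), 0.021 * 30 + (-0.011) * 1)
})

test_that("P(Kiki) is monotone in each predictor with positive slopes", {
  m <- respondent_model_us()
  expect_true(all(diff(response_probability(m, 4:9, 0.2, 1)) > 0))
  expect_true(all(diff(response_probability(m, 6, c(0.1, 0.2, 0.3, 0.4),
                                            1)) > 0))
  expect_true(all(diff(response_probability(m, 6, 0.2, c(0, 1, 30))) > 0))
})

test_that("simulate_group yields one trial per condition per participant", {
  tr <- simulate_group(respondent_model_us(), 10, "US", seed = 11)
  expect_identical(nrow(tr), 720L)
  counts <- table(tr$participant_id)
  expect_true(all(counts == 72))
  # each condition exactly once per participant
  per <- table(tr$participant_id,
               paste(tr$frequency, tr$amplitude, tr$spikiness))
  expect_true(all(per == 1))
  # sound order counterbalanced within participant
  so <- table(tr$participant_id, tr$sound_order)
  expect_true(all(so == 36))
  expect_true(all(tr$response %in% 0:1))
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_group(respondent_model_tw(), 5, "TW", seed = 42)
  b <- simulate_group(respondent_model_tw(), 5, "TW", seed = 42)
  expect_identical(a, b)
  c <- simulate_group(respondent_model_tw(), 5, "TW", seed = 43)
  expect_false(identical(a, c))
  two1 <- simulate_two_groups(respondent_model_us(), respondent_model_tw(),
                              6, 5, seed = 7)
  two2 <- simulate_two_groups(respondent_model_us(), respondent_model_tw(),
                              6, 5, seed = 7)
  expect_identical(two1, two2)
})

test_that("a flat model produces chance-level responding", {
  flat <- respondent_model(0, 0, 0, 0, sigma_id = 0)
  tr <- simulate_group(flat, 200, "US", seed = 99)
  expect_lt(abs(mean(tr$response) - 0.5), 0.01)
})

test_that("Kiki proportion rises with frequency under the US reference model", {
  props <- matrix(0, nrow = 20, ncol = 6)
  for (r in 1:20) {
    tr <- simulate_group(respondent_model_us(), 150, "US", seed = 100 + r)
    props[r, ] <- tapply(tr$response, tr$frequency, mean)
  }
  expect_true(all(diff(colMeans(props)) > 0))
})

test_that("group-specific weightings are recovered directionally", {
  # fixed-effects logistic fits per group; the US amplitude slope should
  # exceed the TW one and the TW spikiness slope the US one in nearly all
  # replicates
  hits <- 0L
  for (r in 1:10) {
    tr <- simulate_two_groups(respondent_model_us(), respondent_model_tw(),
                              40, 40, seed = 200 + r)
    slopes <- sapply(c("US", "TW"), function(g) {
      f <- fit_logistic_mixed(tr[tr$group == g, ], "pooled",
                              random_participant = FALSE)
      f$coefficients[c("amplitude", "spikiness")]
    })
    if (slopes["amplitude", "US"] > slopes["amplitude", "TW"] &&
        slopes["spikiness", "TW"] > slopes["spikiness", "US"])
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("two-group simulation at reference sizes has the full row count", {
  tr <- simulate_two_groups(respondent_model_us(), respondent_model_tw(),
                            150, 88, seed = 1)
  expect_identical(nrow(tr), 17136L)
  expect_identical(sum(tr$group == "US"), 150L * 72L)
})
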