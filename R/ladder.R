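# The three-model comparison ladder: pooled coefficients (Model 1), full
# group-difference set (Model 2), and the delta set without the frequency
# difference (Model 3), compared by deviance / likelihood-ratio tests.

#' Fit the three-model comparison ladder
#'
#' Fits Models 1-3 (see [model_spec()]) to a two-group trial set and records
#' log-likelihood, deviance and parameter count for each. Model 1 pools the
#' groups; Models 2 and 3 let slopes differ between groups through the
#' US-delta terms and add a group random intercept. The models are nested
#' (1 within 3 within 2), so deviances are monotone for converged fits.
#'
#' @param trials a two-group trial data frame.
#' @param coding predictor coding tag.
#' @param nagq quadrature nodes for Model 1 (Models 2-3 have two random
#'   terms and always use the Laplace approximation).
#' @return A list of class `"bk_ladder"` with elements `model1`, `model2`,
#'   `model3` (each a `"bk_fit"`).
#' @export
fit_model_ladder <- function(trials, coding = "default", nagq = 1L) {
  if (length(unique(trials$group)) < 2L)
    stop("the model ladder requires trials from both groups", call. = FALSE)
  structure(
    list(model1 = fit_logistic_mixed(trials, "pooled", coding, nagq = nagq),
         model2 = fit_logistic_mixed(trials, "full", coding),
         model3 = fit_logistic_mixed(trials, "reduced", coding)),
    class = "bk_ladder"
  )
}

#' Likelihood-ratio test of two nested fits
#'
#' The statistic is the deviance difference between the smaller and the
#' larger model; the degrees of freedom are the parameter-count difference
#' (variance components each count as one parameter); the p value comes from
#' the chi-square reference distribution without boundary correction.
#' Tiny negative statistics (within 1e-6, numerical noise) are clamped to
#' zero with a warning.
#'
#' @param fit_small,fit_large `"bk_fit"` objects fitted to the same data,
#'   with `fit_small`'s fixed terms a subset of `fit_large`'s.
#' @return A one-row data frame with `model_small`, `model_large`,
#'   `lr_chi2`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_small, fit_large) {
  if (!inherits(fit_small, "bk_fit") || !inherits(fit_large, "bk_fit"))
    stop("both arguments must be bk_fit objects", call. = FALSE)
  if (!all(fit_small$terms %in% fit_large$terms))
    stop("models are not nested: '", fit_small$model_name,
         "' has terms outside '", fit_large$model_name, "'", call. = FALSE)
  if (fit_small$n_obs != fit_large$n_obs)
    stop("fits are not on the same data (n_obs differ)", call. = FALSE)
  lr <- fit_small$deviance - fit_large$deviance
  if (lr < 0) {
    if (lr > -1e-6) {
      warning("likelihood-ratio statistic slightly negative (", lr,
              "); clamped to 0", call. = FALSE)
      lr <- 0
    } else {
      stop("larger model fits worse than the nested model (lr = ", lr,
           "); check convergence", call. = FALSE)
    }
  }
  df <- fit_large$n_parameters - fit_small$n_parameters
  p <- if (df == 0) as.numeric(lr <= 0) else
    pchisq(lr, df = df, lower.tail = FALSE)
  data.frame(model_small = fit_small$model_id,
             model_large = fit_large$model_id,
             lr_chi2 = lr, df = df, p_value = p)
}

#' Goodness-of-fit and comparison tables for a ladder
#'
#' @param ladder a `"bk_ladder"` from [fit_model_ladder()].
#' @return A list with `fits` (model, df, log-likelihood, deviance) and
#'   `comparisons` (the 1 vs 2, 2 vs 3 and 1 vs 3 likelihood-ratio rows).
#' @export
ladder_table <- function(ladder) {
  if (!inherits(ladder, "bk_ladder"))
    stop("`ladder` must come from fit_model_ladder()", call. = FALSE)
  fits <- data.frame(
    model = 1:3,
    df = vapply(ladder, function(f) f$n_parameters, integer(1)),
    log_likelihood = vapply(ladder, function(f) f$log_likelihood,
                            numeric(1)),
    deviance = vapply(ladder, function(f) f$deviance, numeric(1))
  )
  rownames(fits) <- NULL
  comparisons <- rbind(
    likelihood_ratio_test(ladder$model1, ladder$model2),
    likelihood_ratio_test(ladder$model3, ladder$model2),
    likelihood_ratio_test(ladder$model1, ladder$model3)
  )
  list(fits = fits, comparisons = comparisons)
}

#' @export
print.bk_ladder <- function(x, ...) {
  tb <- ladder_table(x)
  cat("Model comparison ladder\n")
  print(tb$fits, digits = 6, row.names = FALSE)
  cat("\nLikelihood-ratio tests\n")
  print(tb$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}
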