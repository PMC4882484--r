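# Maximum-likelihood logistic mixed-effects fitting (participant random
# intercepts; optionally a group random intercept and US-delta slope terms),
# with Hessian and parametric-bootstrap standard errors and Wald inference.
# Fitting is delegated to lme4::glmer (Laplace approximation by default,
# adaptive Gauss-Hermite quadrature via `nagq` for single-random-effect
# models); degenerate fits without a random term use stats::glm.

.bk_model_ids <- c(pooled = 1L, full = 2L, reduced = 3L)

#' Term structure of the three analysis models
#'
#' * Model 1 (`"pooled"`): constant + frequency + amplitude + spikiness,
#'   participant random intercept; both groups pooled. 5 parameters
#'   (4 fixed + 1 variance).
#' * Model 2 (`"full"`): adds the three US-delta slope terms and a group
#'   random intercept. 9 parameters (7 fixed + 2 variances).
#' * Model 3 (`"reduced"`): as Model 2 without the delta-frequency term.
#'   8 parameters (6 fixed + 2 variances).
#'
#' @param model model id 1/2/3 or name `"pooled"`/`"full"`/`"reduced"`.
#' @return A list with `model_id`, `name`, `fixed_terms`, `delta_terms`,
#'   `random_terms` and `n_parameters`.
#' @export
model_spec <- function(model = 1) {
  if (is.character(model)) {
    name <- match.arg(model, names(.bk_model_ids))
  } else {
    if (!model %in% 1:3) stop("`model` must be 1, 2 or 3", call. = FALSE)
    name <- names(.bk_model_ids)[match(model, .bk_model_ids)]
  }
  deltas <- switch(name,
    pooled = character(0),
    full = c("delta_frequency", "delta_amplitude", "delta_spikiness"),
    reduced = c("delta_amplitude", "delta_spikiness"))
  random <- if (name == "pooled") "participant" else c("participant", "group")
  list(model_id = .bk_model_ids[[name]], name = name,
       fixed_terms = c("constant", "frequency", "amplitude", "spikiness",
                       deltas),
       delta_terms = deltas, random_terms = random,
       n_parameters = 4L + length(deltas) + length(random))
}

#' Build the coded design matrix for one analysis model
#'
#' Applies the predictor coding, and for Models 2 and 3 adds the delta
#' columns as predictor-by-US-indicator interactions (TW is the baseline
#' group, so delta columns are zero for TW rows).
#'
#' @param trials a trial data frame.
#' @param model model id or name, see [model_spec()].
#' @param coding predictor coding tag, see [code_predictors()].
#' @return A data frame with `response`, coded `frequency`, `amplitude`,
#'   `spikiness`, any `delta_*` columns, `participant_id` and `group`.
#' @export
build_design_matrix <- function(trials, model = 1, coding = "default") {
  ms <- model_spec(model)
  req <- c("participant_id", "group", "frequency", "amplitude", "spikiness",
           "response")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  coded <- code_predictors(trials$frequency, trials$amplitude,
                           trials$spikiness, coding)
  d <- data.frame(response = trials$response,
                  frequency = coded$frequency,
                  amplitude = coded$amplitude,
                  spikiness = coded$spikiness,
                  participant_id = trials$participant_id,
                  group = trials$group)
  if (length(ms$delta_terms)) {
    if (length(unique(d$group)) < 2L)
      stop("Models 2 and 3 require trials from both groups", call. = FALSE)
    us <- as.numeric(d$group == "US")
    for (dt in ms$delta_terms) {
      base <- sub("delta_", "", dt)
      d[[dt]] <- d[[base]] * us
    }
  }
  d
}

.bk_formula <- function(ms) {
  fixed <- setdiff(ms$fixed_terms, "constant")
  rand <- c("(1 | participant_id)",
            if ("group" %in% ms$random_terms) "(1 | group)")
  as.formula(paste("response ~ 1 +", paste(c(fixed, rand), collapse = " + ")))
}

#' Fit the logistic mixed-effects model
#'
#' Maximum-likelihood fit of one of the three analysis models (see
#' [model_spec()]) with lme4's `glmer` (binomial family). The Laplace
#' approximation is the default; for single-random-effect models `nagq > 1`
#' selects adaptive Gauss-Hermite quadrature with that many nodes. Setting
#' `random_participant = FALSE` drops the random term entirely and reduces
#' the fit to ordinary logistic regression via `glm` (the degenerate
#' `sigma_id = 0` case).
#'
#' @param trials a trial data frame (one or both groups as the model
#'   requires).
#' @param model model id or name, see [model_spec()].
#' @param coding predictor coding tag.
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes (1 =
#'   Laplace); only honoured for models with a single random term.
#' @param random_participant include the participant random intercept
#'   (default `TRUE`).
#' @return An object of class `"bk_fit"`: coefficients, Hessian standard
#'   errors (`se_hessian`), bootstrap standard errors when computed
#'   (`se_bootstrap`, see [parametric_bootstrap_se()]), Wald 95% confidence
#'   bounds (`ci_lower`, `ci_upper`), `z_values`, `p_values`,
#'   `log_likelihood`, `deviance` (`-2 * log_likelihood`), `n_parameters`,
#'   `variance_components` (random-intercept SDs), `converged`, `singular`
#'   and `n_obs`.
#' @export
fit_logistic_mixed <- function(trials, model = 1, coding = "default",
                               nagq = 1L, random_participant = TRUE) {
  ms <- model_spec(model)
  d <- build_design_matrix(trials, model, coding)
  if (length(unique(d$participant_id)) < 2L && random_participant)
    stop("at least 2 participants are required", call. = FALSE)
  if (length(unique(d$response)) < 2L)
    stop("responses are completely separated: only one outcome present",
         call. = FALSE)
  fixed <- setdiff(ms$fixed_terms, "constant")
  if (random_participant) {
    form <- .bk_formula(ms)
    n_rand <- length(ms$random_terms)
    fit <- lme4::glmer(form, data = d, family = stats::binomial(),
                       nAGQ = if (n_rand == 1L) nagq else 1L,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", unlist(msgs %||% list())))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    varcomp <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
    names(varcomp) <- paste0("sigma_", names(vc))
    n_par <- length(beta) + length(varcomp)
  } else {
    form <- as.formula(paste("response ~ 1 +",
                             paste(fixed, collapse = " + ")))
    fit <- stats::glm(form, data = d, family = stats::binomial())
    converged <- fit$converged
    singular <- FALSE
    beta <- coef(fit)
    varcomp <- numeric(0)
    n_par <- length(beta)
  }
  se <- sqrt(diag(as.matrix(vcov(fit))))
  nm <- c("constant", fixed)
  names(beta) <- names(se) <- nm
  ll <- as.numeric(logLik(fit))
  ci <- wald_ci(beta, se)
  wt <- wald_test(beta, se)
  structure(
    list(coefficients = beta, se_hessian = se, se_bootstrap = NULL,
         ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
         z_values = wt$z, p_values = wt$p,
         log_likelihood = ll, deviance = -2 * ll,
         n_parameters = n_par, variance_components = varcomp,
         converged = converged, singular = singular, n_obs = nrow(d),
         model_id = ms$model_id, model_name = ms$name, coding = coding,
         terms = ms$fixed_terms, nagq = nagq,
         random_participant = random_participant,
         fit = fit, data = d),
    class = "bk_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bk_fit <- function(x, ...) {
  cat(sprintf("Logistic mixed-effects fit (Model %d, '%s'), %d obs\n",
              x$model_id, x$model_name, x$n_obs))
  print(fit_table(x), digits = 4, row.names = FALSE)
  if (length(x$variance_components))
    cat("Random-intercept SDs:",
        paste(sprintf("%s = %.3f", names(x$variance_components),
                      x$variance_components), collapse = ", "), "\n")
  cat(sprintf("logLik %.1f, deviance %.1f, %d parameters%s%s\n",
              x$log_likelihood, x$deviance, x$n_parameters,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular variance]" else ""))
  invisible(x)
}

#' Coefficient table of a fit
#'
#' One row per fixed effect with the coefficient, the reported SE (bootstrap
#' when available, else Hessian), the 95% Wald confidence bounds and the Wald
#' z and p values.
#'
#' @param fit a `"bk_fit"`.
#' @return A data frame.
#' @export
fit_table <- function(fit) {
  se <- fit$se_bootstrap %||% fit$se_hessian
  ci <- wald_ci(fit$coefficients, se)
  wt <- wald_test(fit$coefficients, se)
  data.frame(factor = names(fit$coefficients),
             coefficient = unname(fit$coefficients),
             se = unname(se),
             ci_upper = unname(ci[, "upper"]),
             ci_lower = unname(ci[, "lower"]),
             z = unname(wt$z), p = unname(wt$p),
             se_type = if (is.null(fit$se_bootstrap)) "hessian"
                       else "bootstrap")
}

#' Parametric-bootstrap standard errors
#'
#' Simulates `n_boot` response vectors from the fitted model -- fixed effects
#' at their estimates, random intercepts freshly drawn from the estimated
#' variance components -- over the original design, refits each replicate,
#' and takes the across-replicate standard deviation of every coefficient.
#' Replicates whose refit fails or does not converge are dropped and counted;
#' a warning is raised when more than 10% are dropped.
#'
#' @param fit a converged `"bk_fit"`.
#' @param n_boot number of bootstrap replicates (>= 50; default 200).
#' @param seed integer seed; identical seeds give identical SE maps.
#' @return The fit with `se_bootstrap` (named vector) filled in, plus
#'   attributes `n_boot_dropped` and `n_boot` on that vector.
#' @export
parametric_bootstrap_se <- function(fit, n_boot = 200L, seed = 1L) {
  if (!inherits(fit, "bk_fit")) stop("`fit` must be a bk_fit", call. = FALSE)
  if (!fit$converged)
    stop("refusing to bootstrap a non-converged fit", call. = FALSE)
  if (n_boot < 50) stop("`n_boot` must be >= 50", call. = FALSE)
  set.seed(seed)
  # use.u = FALSE draws new random intercepts per replicate: the parametric
  # bootstrap of the marginal model
  sims <- if (fit$random_participant) {
    simulate(fit$fit, nsim = n_boot, use.u = FALSE)
  } else {
    simulate(fit$fit, nsim = n_boot)
  }
  p <- length(fit$coefficients)
  est <- matrix(NA_real_, nrow = n_boot, ncol = p)
  for (b in seq_len(n_boot)) {
    res <- tryCatch(suppressMessages(suppressWarnings({
      if (fit$random_participant) {
        r <- lme4::refit(fit$fit, newresp = sims[[b]])
        msgs <- unlist(r@optinfo$conv$lme4$messages %||% list())
        if (r@optinfo$conv$opt != 0 ||
            any(grepl("failed to converge", msgs))) NULL else lme4::fixef(r)
      } else {
        d2 <- fit$data
        d2$response <- sims[[b]]
        r <- stats::glm(stats::formula(fit$fit), data = d2,
                        family = stats::binomial())
        if (!r$converged) NULL else coef(r)
      }
    })), error = function(e) NULL)
    if (!is.null(res)) est[b, ] <- res
  }
  ok <- stats::complete.cases(est)
  dropped <- sum(!ok)
  if (dropped > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates dropped", dropped,
                    n_boot), call. = FALSE)
  se <- apply(est[ok, , drop = FALSE], 2, sd)
  names(se) <- names(fit$coefficients)
  attr(se, "n_boot") <- n_boot
  attr(se, "n_boot_dropped") <- dropped
  fit$se_bootstrap <- se
  fit
}

#' Wald 95% confidence interval
#'
#' `coefficient +/- 1.96 * se`, with the conventional constant 1.96 rather
#' than a refined normal quantile.
#'
#' @param coefficient estimate(s).
#' @param se standard error(s), > 0.
#' @return A matrix with columns `lower` and `upper`.
#' @export
wald_ci <- function(coefficient, se) {
  if (any(se <= 0)) stop("`se` must be > 0", call. = FALSE)
  cbind(lower = coefficient - 1.96 * se, upper = coefficient + 1.96 * se)
}

#' Wald z test against zero
#'
#' @inheritParams wald_ci
#' @return A list with `z = coefficient / se` and two-sided normal `p`.
#' @export
wald_test <- function(coefficient, se) {
  if (any(se <= 0)) stop("`se` must be > 0", call. = FALSE)
  z <- coefficient / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}
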