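# Generative logistic model for two-alternative forced-choice Bouba/Kiki
# responses, with per-participant random intercepts and optional
# group-difference (delta) slopes.

#' Specify a generative respondent model
#'
#' Responses are Bernoulli draws on the logit scale:
#' `logit P(Kiki) = beta0 + b_i + (beta + delta * 1[group == "US"]) . coded`,
#' where `b_i ~ Normal(0, sigma_id^2)` is a participant-specific response
#' bias, `coded` are the coded frequency/amplitude/spikiness predictors (see
#' [code_predictors()]), and the delta terms are slope increments for the US
#' group relative to the Taiwanese (TW) baseline.
#'
#' @param beta0 intercept, logit units.
#' @param beta_frequency,beta_amplitude,beta_spikiness fixed-effect slopes
#'   per coded predictor unit.
#' @param delta_frequency,delta_amplitude,delta_spikiness US-minus-TW slope
#'   increments (0 when the groups share a slope).
#' @param sigma_id SD of participant random intercepts (>= 0, logit units).
#' @param sigma_group SD of group random intercepts (>= 0; used only by the
#'   combined two-group models).
#' @param coding predictor coding tag, see [code_predictors()].
#' @return An object of class `"respondent_model"`.
#' @export
respondent_model <- function(beta0, beta_frequency, beta_amplitude,
                             beta_spikiness, delta_frequency = 0,
                             delta_amplitude = 0, delta_spikiness = 0,
                             sigma_id = 1, sigma_group = 0,
                             coding = "default") {
  if (sigma_id < 0 || sigma_group < 0)
    stop("random-intercept SDs must be >= 0", call. = FALSE)
  structure(
    list(beta0 = beta0, beta_frequency = beta_frequency,
         beta_amplitude = beta_amplitude, beta_spikiness = beta_spikiness,
         delta_frequency = delta_frequency, delta_amplitude = delta_amplitude,
         delta_spikiness = delta_spikiness, sigma_id = sigma_id,
         sigma_group = sigma_group, coding = coding),
    class = "respondent_model"
  )
}

#' @export
print.respondent_model <- function(x, ...) {
  cat("Generative logistic respondent model (logit scale)\n")
  cat(sprintf("  constant %.3f, frequency %.3f, amplitude %.3f, spikiness %.3f\n",
              x$beta0, x$beta_frequency, x$beta_amplitude, x$beta_spikiness))
  if (any(c(x$delta_frequency, x$delta_amplitude, x$delta_spikiness) != 0))
    cat(sprintf("  US deltas: frequency %+.3f, amplitude %+.3f, spikiness %+.3f\n",
                x$delta_frequency, x$delta_amplitude, x$delta_spikiness))
  cat(sprintf("  sigma_id %.2f, sigma_group %.2f, coding '%s'\n",
              x$sigma_id, x$sigma_group, x$coding))
  invisible(x)
}

#' Reference coefficient sets
#'
#' Canned generative models using the package's reference estimates for the
#' two samples. `respondent_model_us()` and `respondent_model_tw()` carry the
#' separate per-group fits (US-style respondents weight amplitude more
#' heavily; Taiwanese-style respondents weight spikiness more heavily).
#' `respondent_model_combined()` carries the combined two-group fit in which
#' both groups share the frequency slope and the US group receives amplitude
#' and spikiness slope increments.
#'
#' @param sigma_id SD of participant random intercepts; the reference
#'   analyses never report it, so the package default of 1.0 logit unit is
#'   used as a realistic inter-subject spread.
#' @return A [respondent_model()].
#' @export
respondent_model_us <- function(sigma_id = 1) {
  respondent_model(beta0 = -4.835, beta_frequency = 0.394,
                   beta_amplitude = 0.089, beta_spikiness = 0.014,
                   sigma_id = sigma_id)
}

#' @rdname respondent_model_us
#' @export
respondent_model_tw <- function(sigma_id = 1) {
  respondent_model(beta0 = -4.247, beta_frequency = 0.373,
                   beta_amplitude = 0.066, beta_spikiness = 0.024,
                   sigma_id = sigma_id)
}

#' @rdname respondent_model_us
#' @param delta_frequency US-minus-TW frequency-slope increment; 0 in the
#'   combined reference fit (the groups share the frequency slope).
#' @export
respondent_model_combined <- function(sigma_id = 1, delta_frequency = 0) {
  respondent_model(beta0 = -4.567, beta_frequency = 0.386,
                   beta_amplitude = 0.067, beta_spikiness = 0.025,
                   delta_frequency = delta_frequency,
                   delta_amplitude = 0.021, delta_spikiness = -0.011,
                   sigma_id = sigma_id)
}

#' Code the design predictors
#'
#' The `"default"` coding leaves frequency on its raw level scale (4-9),
#' multiplies amplitude by 100 (10-40) and leaves spikiness raw (0, 1, 30);
#' on this scale the reference coefficient sets span response probabilities
#' from well below to well above chance over the design. The `"identity"`
#' coding passes all three predictors through unchanged.
#'
#' @param frequency,amplitude,spikiness design levels (vectorized).
#' @param coding `"default"` or `"identity"`.
#' @return A data frame with coded columns `frequency`, `amplitude`,
#'   `spikiness`.
#' @examples
#' code_predictors(4, 0.1, 0)   # 4, 10, 0
#' @export
code_predictors <- function(frequency, amplitude, spikiness,
                            coding = c("default", "identity")) {
  coding <- match.arg(coding)
  if (coding == "default") amplitude <- amplitude * 100
  data.frame(frequency = frequency, amplitude = amplitude,
             spikiness = spikiness)
}

#' Probability of a "Kiki" response
#'
#' Inverse-logit of the linear predictor of a [respondent_model()] for given
#' design levels, group and participant random intercept.
#'
#' @param model a [respondent_model()].
#' @param frequency,amplitude,spikiness design levels (vectorized).
#' @param group `"US"` or `"TW"`; delta slopes apply to the US group.
#' @param b participant random intercept(s), logit units.
#' @return Probabilities strictly in (0, 1).
#' @examples
#' response_probability(respondent_model_us(), 9, 0.4, 30)
#' @export
response_probability <- function(model, frequency, amplitude, spikiness,
                                 group = "TW", b = 0) {
  if (!inherits(model, "respondent_model"))
    stop("`model` must be a respondent_model", call. = FALSE)
  if (!all(group %in% c("US", "TW")))
    stop("`group` must be 'US' or 'TW'", call. = FALSE)
  coded <- code_predictors(frequency, amplitude, spikiness, model$coding)
  us <- as.numeric(group == "US")
  eta <- model$beta0 + b +
    (model$beta_frequency + model$delta_frequency * us) * coded$frequency +
    (model$beta_amplitude + model$delta_amplitude * us) * coded$amplitude +
    (model$beta_spikiness + model$delta_spikiness * us) * coded$spikiness
  plogis(eta)
}

#' Simulate one group of respondents
#'
#' Draws a participant random intercept `b_i ~ Normal(0, sigma_id^2)` for each
#' respondent, then one Bernoulli forced-choice response per design condition,
#' presented in a per-participant randomized order with the sound order
#' ("Bouba first" `BK` vs "Kiki first" `KB`) counterbalanced across the
#' trials of each participant. The sound order carries no effect in the
#' generative model.
#'
#' @param model a [respondent_model()].
#' @param n_participants number of respondents (>= 1).
#' @param group group label, `"US"` or `"TW"`.
#' @param design a [stimulus_design()].
#' @param seed integer seed; identical seeds give identical data.
#' @param id_prefix prefix for participant identifiers (defaults to the
#'   group label).
#' @return A trial data frame with columns `participant_id`, `group`,
#'   `frequency`, `amplitude`, `spikiness`, `sound_order`, `response`
#'   (0 = Bouba, 1 = Kiki), in presentation order within participant.
#' @export
simulate_group <- function(model, n_participants, group = c("US", "TW"),
                           design = stimulus_design(), seed = NULL,
                           id_prefix = NULL) {
  if (!inherits(model, "respondent_model"))
    stop("`model` must be a respondent_model", call. = FALSE)
  if (n_participants < 1)
    stop("`n_participants` must be >= 1", call. = FALSE)
  group <- match.arg(group)
  if (is.null(id_prefix)) id_prefix <- group
  if (!is.null(seed)) set.seed(seed)
  grid <- design_grid(design)
  n_cond <- nrow(grid)
  b <- rnorm(n_participants, 0, model$sigma_id)
  out <- vector("list", n_participants)
  sound_cycle <- rep_len(c("BK", "KB"), n_cond)
  for (i in seq_len(n_participants)) {
    ord <- sample.int(n_cond)
    d <- grid[ord, , drop = FALSE]
    p <- response_probability(model, d$frequency, d$amplitude, d$spikiness,
                              group = group, b = b[i])
    out[[i]] <- data.frame(
      participant_id = sprintf("%s%04d", id_prefix, i),
      group = group,
      frequency = d$frequency,
      amplitude = d$amplitude,
      spikiness = d$spikiness,
      sound_order = sound_cycle,
      response = rbinom(n_cond, 1L, p)
    )
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  trials
}

#' Simulate both respondent groups
#'
#' Concatenates a US and a TW [simulate_group()] run with sub-seeds derived
#' deterministically from `seed`. Passing the same model object for both
#' groups with zero delta terms gives a shared-coefficient null simulation.
#'
#' @param model_us,model_tw [respondent_model()] objects for the two groups.
#'   A model's delta terms apply only when it simulates the US group.
#' @param n_us,n_tw group sizes (defaults: the 150 / 88 reference sample
#'   sizes).
#' @param design a [stimulus_design()].
#' @param seed integer seed.
#' @return A trial data frame (see [simulate_group()]) with
#'   `(n_us + n_tw) * nrow(design_grid(design))` rows.
#' @export
simulate_two_groups <- function(model_us, model_tw, n_us = 150, n_tw = 88,
                                design = stimulus_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2L)
  rbind(
    simulate_group(model_us, n_us, "US", design = design, seed = sub[1L]),
    simulate_group(model_tw, n_tw, "TW", design = design, seed = sub[2L])
  )
}
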