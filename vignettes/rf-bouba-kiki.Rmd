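---
title: "Radial-frequency shapes and the Bouba/Kiki correspondence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-frequency shapes and the Bouba/Kiki correspondence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boubakit)
```

## The scientific problem

Most people map the nonsense word "Bouba" onto rounded outlines and "Kiki"
onto angular ones. boubakit studies this sound-shape correspondence with
*radial frequency* (RF) patterns: closed contours whose radius is a
sinusoidal function of polar angle. RF patterns put the visual side of the
correspondence on a parametric footing — three attributes can be moved
independently, step by step:

* **frequency** (cycles per revolution = number of lobes),
* **amplitude** (fractional radial modulation depth), and
* **spikiness** (triangular-wave harmonics added above the fundamental,
  sharpening each lobe toward a spike).

The package covers the full workflow around a two-group, two-alternative
forced-choice experiment (a US-style and a Taiwan-style sample): stimulus
generation, response simulation, per-condition agreement maps, logistic
mixed-model fitting, and a three-model comparison that quantifies which
attribute weightings differ between groups.

## Stimulus geometry

The radius profile of one pattern is

$$ r(\theta) = r_{mean}\,\big(1 + A\, m(\theta)\big), \qquad
   m(\theta) = \frac{1}{c_k}\sum_{j=0}^{k}
   \frac{(-1)^j}{(2j+1)^2}\,\sin\!\big((2j+1)(\omega\theta+\varphi)\big), $$

the truncated Fourier series of a triangle wave with $k$ harmonics above the
fundamental. Because every term of the series peaks simultaneously at
$\omega\theta + \varphi = \pi/2$, the truncated series attains its maximum
$c_k = \sum_{j \le k} (2j+1)^{-2}$ there exactly, and dividing by $c_k$
normalizes the modulator to unit peak. This normalization is a deliberate
design choice (and can be switched off in `triangular_modulator()`): it
makes $A$ equal the maximum fractional radial deviation at *every*
spikiness level, so the amplitude and spikiness factors stay comparable
when crossed factorially. At $k = 0$ the modulator is exactly
$\sin(\omega\theta + \varphi)$.

The default design crosses frequencies 4–9, amplitudes 0.1–0.4 and
spikiness 0/1/30 into 72 conditions. Phase is fixed at 0 for the factorial
stimuli — it only rotates the shape, and rotation is perceptually inert
here. `composite_preset()` builds the classic rounded/angular control pair
by superimposing five pure components (frequencies 7–35, amplitudes
0.4–0.025) with peak alignment ("angular") or alternating trough alignment
("rounded"):

```{r presets}
radius_profile(composite_preset("angular"), 0)   # 1 + .4 + .2 + .1 + .05 + .025
radius_profile(composite_preset("rounded"), 0)   # 1 + .4 - .2 + .1 - .05 + .025
count_lobes(sample_contour(composite_preset("angular")))
```

Contours are sampled on 4096 uniform angles of $[0, 2\pi)$ by default
(closed by duplicating the first vertex) — enough that lobe counting and
rendering are exact for every design condition while keeping files small.
Rendering uses the mathematical y-up convention internally and flips to
image coordinates only at export; both the native SVG writer and the
direct-rasterization PNG writer are byte-deterministic.

## The generative response model

Simulated respondents follow a logistic model with a participant random
intercept:

$$ \mathrm{logit}\, P(\text{Kiki}) = \beta_0 + b_i
   + (\beta_F + \Delta_F u)\,F + (\beta_A + \Delta_A u)\,A^{c}
   + (\beta_S + \Delta_S u)\,S, \qquad b_i \sim N(0, \sigma_{id}^2), $$

where $u$ indicates the US group (TW is the baseline) and the coded
predictors are frequency raw (4–9), amplitude times 100 (10–40) and
spikiness raw (0/1/30). The $\times 100$ amplitude coding is the one under
which the package's reference coefficient sets span response probabilities
from well below to well above chance over the design (the linear predictor
runs from about $-2.4$ to $+2.7$ for the US set); an identity coding is
also selectable.

Three reference coefficient sets ship with the package:
`respondent_model_us()` ($\beta_0=-4.835$, $\beta_F=0.394$,
$\beta_A=0.089$, $\beta_S=0.014$), `respondent_model_tw()`
($-4.247, 0.373, 0.066, 0.024$) and `respondent_model_combined()`
(shared slopes $-4.567, 0.386, 0.067, 0.025$ with US increments
$\Delta_A=0.021$, $\Delta_S=-0.011$ and $\Delta_F=0$). The sign convention
for the $\Delta$ terms — US indicator over a TW baseline — is chosen so
that a positive $\Delta_A$ means the US group weights amplitude more
heavily, matching the direction of the per-group sets.

Two generator choices are worth stating explicitly:

* $\sigma_{id} = 1$ logit unit by default. The reference analyses never
  report the random-intercept variance, so the package fixes a value that
  produces realistic inter-subject spread (about $\pm 2$ logit units for
  95% of respondents) and uses it consistently everywhere, including in
  all recovery simulations.
* The sound order (`BK`/`KB`) is counterbalanced across each participant's
  randomized trial sequence but carries no effect in the model; it is kept
  in the trial schema because the experimental procedure counterbalances
  it.

What the simulator does *not* emulate: response times, age or other
demographics, order effects, lapses/attention failures, and any response
process for the two control shapes (no generative coefficients exist for
them). Passing recovery tests therefore show that the analysis chain is
consistent with its own generative assumptions at the study's sample
sizes — not that real respondents satisfy those assumptions.

```{r simulate}
trials <- simulate_two_groups(respondent_model_us(), respondent_model_tw(),
                              n_us = 150, n_tw = 88, seed = 1)
nrow(trials)   # 238 participants x 72 trials
head(trials, 3)
```

## Agreement maps

For each design cell, trials are pooled across participants and the Kiki
tally is tested against chance (50%) with a one-degree-of-freedom Pearson
chi-square without continuity correction,
$\chi^2 = (2k - n)^2 / n$. A cell is labelled *Kiki* (proportion above 0.5,
$p < .05$), *Bouba* (below 0.5, $p < .05$) or *undetermined*; saturation
bands at $p < .05 / .01 / .001$ drive the figure colours. No
multiple-testing correction is applied — cells are reported individually,
and the mixed model is the correlation-aware analysis. An exact binomial
test is available (`classify_cell(..., exact = TRUE)`) and serves as the
oracle in the test suite; the two tests can only disagree for tallies whose
p value straddles the 0.05 threshold, the usual discrete-versus-asymptotic
boundary case.

```{r agreement}
cells <- agreement_matrix(trials, group = "US")
table(cells$label)
```

## Mixed-model fitting and inference

`fit_logistic_mixed()` maximizes the marginal likelihood with `lme4::glmer`
(binomial family). The Laplace approximation is the default; for models
with a single random term, `nagq` switches to adaptive Gauss–Hermite
quadrature, and the test suite verifies the reported log-likelihood against
brute-force trapezoid integration of the random intercept (20,001 nodes per
cluster) to $10^{-4}$ on 5-subject toy instances. Convergence is flagged,
never silent; complete separation raises a diagnostic error. Setting
`random_participant = FALSE` drops the random term and reduces the fit to
ordinary logistic regression — the degenerate $\sigma_{id} = 0$ case, which
the tests compare against a direct `glm` fit.

Confidence intervals use the conventional constant:
$\text{estimate} \pm 1.96 \cdot SE$, not a refined normal quantile, and
Wald $z = \text{estimate}/SE$ with a two-sided normal p value.

`parametric_bootstrap_se()` simulates response vectors from the fitted
model — fixed effects at their estimates, random intercepts freshly drawn —
refits each, and reports the across-replicate standard deviation of every
coefficient. The default is 200 replicates: at desk scale the bootstrap and
Hessian SEs agree well within sampling noise, and the replicate count is a
plain argument for anyone who wants more. Replicates that fail to converge
are dropped and counted, with a warning beyond 10%. When bootstrap SEs are
present they are the reported SEs; Hessian SEs are always stored alongside.

## The model ladder

Three nested models formalize the cross-cultural question:

| Model | fixed terms | random terms | parameters |
|---|---|---|---|
| 1 | constant, F, A, S | participant | 5 |
| 2 | + $\Delta_F, \Delta_A, \Delta_S$ | participant, group | 9 |
| 3 | + $\Delta_A, \Delta_S$ (no $\Delta_F$) | participant, group | 8 |

$\Delta$ columns are predictor-by-US-indicator interactions. The group
random intercept has only two levels, which is variance-degenerate in
general; it is kept because the combined-model specification calls for it,
`lme4` handles the boundary by estimating the variance at (or near) zero,
and the fit is flagged `singular` rather than altered. Parameter counting
always treats each variance component as one parameter (hence 5/9/8), and
likelihood-ratio tests use the plain chi-square reference without boundary
correction — deviance differences with df equal to the parameter-count
difference. Tiny negative LR statistics (within $10^{-6}$) are clamped to
zero with a warning; anything more negative is a convergence error and is
raised as such.

```{r ladder, eval = FALSE}
ladder <- fit_model_ladder(trials)
ladder_table(ladder)
```

## Numerical and design choices

* **Optimizer.** `glmer` defaults, with post-fit derivative checks
  disabled (`calc.derivs = FALSE`): at these data sizes the checks cost
  roughly as much as the fit and flag spurious gradient tolerances;
  convergence is instead taken from the optimizer return code.
* **Determinism.** Every stochastic entry point takes a seed;
  `simulate_two_groups` derives the two group sub-seeds from one seed;
  `run_full_analysis` reports are byte-identical across reruns of one
  configuration, and the report embeds an MD5 hash of the serialized
  configuration.
* **Degenerate inputs.** Zero-trial cells are flagged missing, never
  fabricated; single-outcome responses raise a separation error; invalid
  trial CSV rows are reported with row numbers.
* **Problem sizes.** The test suite runs recovery at the reference sample
  sizes (150 and 88 participants, 20 replicates), Wald-calibration runs at
  25 + 25 participants (100 replicates), CI-coverage runs at 20
  participants (60 replicates), and likelihood-oracle runs at 5
  participants — sizes chosen so each check has the power it needs while
  the whole suite stays comfortably desk-scale.

## Known limitations

* The agreement maps pool trials across participants, ignoring
  within-participant correlation by design; only the mixed models account
  for it.
* The two-level group random intercept is retained for fidelity to the
  combined-model specification but is usually singular; its variance
  should not be interpreted.
* Parameter recovery validates internal consistency of the pipeline under
  the generative model; cultural inference from real data needs the real
  data.
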