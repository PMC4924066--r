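---
title: "Hourly crash-frequency panel models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hourly crash-frequency panel models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zinbre)
```

## The modeling problem

Crash counts on highway segments observed at an hourly scale are dominated
by zeros: on the I-25 corridor that motivates this package, 99.6% of
segment-hours record no crash, the mean hourly count is 0.004 and the
maximum is 4.  Two features of such data break the ordinary Poisson
regression setting:

* **Overdispersion.** The variance of the counts exceeds the mean.  The
  negative binomial (NB) model introduces a gamma-distributed
  multiplicative heterogeneity with overdispersion parameter $\alpha$,
  giving $\mathrm{Var}(n) = \lambda(1 + \alpha\lambda)$ and recovering
  Poisson as $\alpha \to 0$.
* **Excess zeros.** Many segment-hours are plausibly *virtually safe* —
  free-flowing traffic, dry pavement, daylight — and contribute zeros by a
  different mechanism than the chance absence of a crash in a risky hour.
  The zero-inflated NB (ZINB) mixture makes this explicit: with
  probability $q_{it}$ the segment-hour sits in a structural zero state,
  otherwise the count is NB.

With hourly panels, the same segment contributes thousands of correlated
observations.  The package's top model therefore adds independent normal
site-specific random effects to both mixture states:

$$\lambda_{it} = \exp(\beta_{NB} X_{NB,it} + \sigma_i), \qquad
  \operatorname{logit}(q_{it}) = \beta_z X_{z,it} + \psi_i,$$

with $\sigma_i \sim N(0, \varphi_\sigma^2)$ and
$\psi_i \sim N(0, \varphi_\psi^2)$ independent.  The likelihood of site
$i$ marginalizes the effects:

$$L_i = \int\!\!\int \prod_{t=1}^{t_i}
  P_{ZINB}\!\left(n_{it} \mid \lambda_{it}(\sigma), q_{it}(\psi),
  \alpha\right)\, d N(\sigma; 0, \varphi_\sigma^2)\,
  dN(\psi; 0, \varphi_\psi^2),$$

and the panel log-likelihood is $\sum_i \log L_i$ over the $I$ sites with
$N = \sum_i t_i$ observations.  The panel is *unbalanced*: $t_i$ differs
across sites because monitoring stations go down for stretches of time;
nothing in the likelihood requires balance.

## Estimation

`fit_crash_model()` estimates the ladder `poisson`, `nb`, `zip`, `zinb`,
`zinb_re` by maximum (marginal) likelihood:

* **Quadrature.** The normal integrals are evaluated by non-adaptive
  Gauss–Hermite quadrature, by default 15 nodes per random dimension and
  a product rule when both states carry effects.  A site's integrand is a
  product of up to thousands of masses, so all arithmetic is in log space
  with log-sum-exp across nodes; $\varphi = 0$ collapses the integral to
  a point mass exactly rather than approximately.  Non-adaptive nodes are
  adequate here because the site posteriors are wide — each site
  contributes only a handful of crashes — and the choice is test-gated:
  order 31 agrees with order 63 to $10^{-8}$ and with brute-force
  Monte-Carlo integration to $10^{-3}$ on reference cases.
* **Parameterization.** $\log\alpha$, $\log\varphi_\sigma$,
  $\log\varphi_\psi$ are unconstrained internally, guaranteeing
  positivity; estimates and delta-method standard errors are reported on
  the natural scale.  Transforms are clamped (at $e^{\pm 25}$) so
  line-search excursions cannot overflow $1/\alpha$.
* **Staged initialization.** Zero-inflated likelihoods are multimodal, so
  each model starts from the previous rung: Poisson slopes (intercept at
  the log sample mean, which for the intercept-only model *is* the MLE)
  seed NB with a method-of-moments $\alpha$; the NB fit plus the excess-
  zero fraction seeds the zero-state intercept (and deflates the count
  intercept by $-\log(1-q_0)$ to preserve the mean); the spread of
  site-level observed/expected log ratios seeds $\varphi$.
* **Optimizer.** BFGS with the analytic gradient of the marginal
  likelihood (the quadrature weights double as posterior node weights, so
  the gradient is an exact weighted score).  The full-memory update
  matters: the surface is ill-conditioned when $\alpha$ is weakly
  identified, and limited-memory variants need several times as many
  evaluations on the same problems.
* **Boundary fits.** $\hat\alpha \to 0$ or $\hat\varphi \to 0$ are
  reported at the boundary with a `boundary` flag.  Boundary parameters
  are profiled out of the observed-information matrix and reported
  without a standard error — a Wald SE at a boundary would be
  meaningless — while the remaining parameters keep proper SEs.  A
  non-positive-definite information matrix falls back to a flagged
  pseudo-inverse.

Standard errors come from a central finite-difference Hessian of the
analytic gradient (step $10^{-4}$, relative); halving the step moves SEs
by less than 0.1% on reference fits.  `information_criteria()` reports
$-2\ell$, AIC $= -2\ell + 2k$ and BIC $= -2\ell + k\log N$ with $k$ the
free parameters of the configuration.

The package deliberately does **not** automate covariate selection: the
screening of candidate variables at $p < 0.1$ that produced the reference
specification is a modeling judgment, so the design lists are user input
and the fit reports p-values.

## Model choice

`vuong_test()` computes the per-observation log-density ratio
$m_{it} = \log f_1(y_{it}|X_{it}) - \log f_2(y_{it}|X_{it})$ between a
zero-inflated fit and its parent and the statistic
$V = \bar m \sqrt{N} / S_m$, asymptotically standard normal; $V > 1.96$
favors the zero-inflated specification at the 95% level.  For
random-effects fits the per-observation density integrates the site
effect out *at the observation level* with the fitted $\varphi$ — the
statistic is defined on observation-wise densities, and this choice (over
conditioning on a site's whole history) is recorded in the result; both
the pooled and random-effects comparisons are available.
`overdispersion_decision()` reports $\hat\alpha$, its t-statistic and the
NB-vs-Poisson preference, with a boundary note when $\hat\alpha$ sits at
zero.

## Elasticities

For a covariate only in the count state, the expected count
$E(n) = (1-q)\lambda$ is log-linear in it, so the elasticity of a
continuous covariate evaluated at the sample mean is $\beta \bar x$, and
the relative effect of an indicator switching on is $1 - e^{-\beta}$.
These closed forms reproduce all nine count-state-only entries of the
reference study's elasticity table from its printed coefficients and
means to within one unit in the third printed decimal (the printed inputs
are themselves rounded, which is exactly the attainable agreement).  For
covariates in the zero state or in both states the elasticity depends on
the observation-level distribution of $q_{it}$; `elasticity_observed()`
averages the row-wise elasticity
$x_{it}(\beta_{NB} - \beta_z q_{it})$ (continuous) or the row-wise
relative change under a 0→1 toggle (indicators), and
`elasticity_report()` labels which method produced each number.  Values
for multi-state covariates are *not* claimed to match the reference table
— they cannot be computed from printed summaries alone.

## The synthetic generator

The original panel is not deposited, so `generate_panel()` produces
synthetic panels with the study's structure; every default is pinned to a
published quantity:

* 57 segments × 8760 hours, thinned by per-site random outage blocks
  (Poisson(6) blocks with exponential lengths scaled so the expected
  retained fraction is $328{,}529/(57 \cdot 8760) \approx 0.658$) —
  missing completely at random with respect to counts, mimicking station
  downtime, and guaranteeing unbalanced $t_i$.
* Site-constant geometry (speed limit, lanes, segment length, ramps,
  curvature, rutting, pavement, medians, shoulders, grade) drawn once per
  site; hour-varying weather and traffic per segment-hour; temporal
  indicators from a deterministic hour-of-day calendar (night
  20:00–05:59, sunset around 18–20h, the 4–5 am hour) with November days
  shared across sites.
* Continuous covariates use truncated normals whose *underlying*
  parameters are solved so the truncated moments match the published
  mean/sd at the published min–max (naive truncation would distort
  heavily truncated variables).  Three variables need non-normal shapes
  dictated by their printed moments: visibility is a clear/fog-event
  mixture (3.85% fog hours), the speed-limit-minus-speed gap a
  free-flow/congestion mixture (13% congested hours), traffic volume a
  lognormal, and median width a narrow/wide-median mixture.
* Counts are drawn forward from the model: structural zero with
  probability $q_{it}$, otherwise a gamma-mixed Poisson NB draw, with the
  latent state recorded per row.  The default truth is the published
  coefficient set ($\alpha = 1.818$, $\varphi_\sigma = 0.484$); the
  remaining published covariates are generated with zero coefficients so
  false-positive behavior can be probed.

Under these defaults the generator reproduces the headline structure it
emulates — ≈99.6% zeros, mean hourly count ≈0.004, single-digit maxima —
without any of those three quantities being targeted directly.

**What the generator does not emulate:** covariates are independent across
blocks (the published marginals cannot identify their joint dependence),
weather is not spatially shared between neighboring sites, there is no
serial correlation within a site beyond the random effect, and outages
are MCAR.  One visible consequence of covariate independence is a
slightly heavier extreme-count tail than the real corridor's (rare
double-digit segment-hours can occur at full panel size, where the
observed panel's maximum was 4): in the real data the covariate
combinations that would multiply the rate most aggressively do not
co-occur.  Passing recovery tests on this generator therefore shows the
estimator is correct *under the model's own assumptions*, not that those
assumptions hold on any particular corridor.

## Verification scale and reproducibility

All randomness flows through explicit seeds.  The test suite sizes its
simulations for a desk machine:

* parameter recovery: 20 replicates of the 57-site scenario at a reduced
  horizon of 2,000 hours/site (~75k observations, ~200–300 crashes per
  replicate), fitted with quadrature order 7 — on these panels order 7
  agrees with order 31 to about $2\times10^{-3}$ in log-likelihood, far
  inside the sampling noise.  At this reduced event count the
  overdispersion $\alpha$ is only weakly identified (it occasionally
  collapses to its boundary), which is a property of the scenario's
  information content, not of the optimizer; coverage is therefore
  assessed on the regression coefficients, whose reported ±3 SE intervals
  should (and do) cover the generating values in ≥90% of replicates.
* Vuong behavior: 100 replicates per arm at N = 20,000 on a compact
  two-covariate scenario with heavy inflation ($q \approx 0.5$), and a
  matching plain-NB arm for approximate size control.
* Oracle equivalences (quadrature vs $10^6$-draw Monte-Carlo integration,
  pmf vs gamma-mixed Poisson sampling) run at $10^6$ draws.

## Known limitations

* Non-adaptive quadrature can lose accuracy if a site accumulates very
  many events (sharp posterior); adaptive centering would be the natural
  extension.
* Wald standard errors and the profiled-out treatment of boundary
  parameters are first-order tools; likelihood-ratio or bootstrap
  intervals would be preferable near boundaries.
* If both $\sigma_i$ and $\psi_i$ are requested they are taken as
  independent, as stated in the model; a correlated-effects variant is
  out of scope.
* The two-state mixture is not the only reading of excess zeros;
  generalized ordered-response alternatives are deliberately not
  implemented.
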