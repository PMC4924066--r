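# zinbre

Zero-inflated negative binomial panel models with site-specific random
effects, for crash-frequency analysis at refined temporal scales.

## The problem

Hourly crash counts on highway segments are panel count data with two
awkward properties: they are massively zero-dominated (on the I-25
corridor that motivates this package, 99.6% of segment-hours have no
crash, the mean count is 0.004 crashes/hour) and repeated observations of
the same segment share unobserved risk factors.  `zinbre` is for road
safety analysts and count-model methodologists who want to fit, compare
and interpret the model ladder

Poisson → NB → ZIP → ZINB → ZINB with site random effects

on unbalanced panels, where the top model is

```
n_it ~ 0                      with prob  q_it        (virtually safe state)
n_it ~ NB(lambda_it, alpha)   with prob  1 - q_it    (count state)

lambda_it     = exp(beta_NB' X_NB,it + sigma_i),   sigma_i ~ N(0, phi_sigma^2)
logit(q_it)   = beta_z'  X_z,it  + psi_i,          psi_i   ~ N(0, phi_psi^2)
```

Estimation is by maximum marginal likelihood: the independent normal site
effects are integrated out with Gauss–Hermite quadrature, in log space,
with analytic gradients.  Model choice is supported by the Vuong
non-nested test for zero inflation, `V = mean(m) * sqrt(N) / sd(m)` on
the per-observation log-density ratios `m_it`, and by an overdispersion
decision on `alpha`.  Post-estimation elasticities quantify covariate
effects on the expected count `E(n) = (1 - q) * lambda`: `beta * xbar`
for count-state continuous covariates, `1 - exp(-beta)` for count-state
indicators, and an observation-averaged method for covariates in the zero
state or in both states.

Because the original I-25 panel is not deposited, the package ships a
calibrated synthetic generator (`generate_panel()`) reproducing its
structure: 57 segments, up to 365×24 hourly rows each with random station
outages (≈ 66% retained), covariates matched to the published summary
moments, and counts drawn forward from the published coefficient set —
yielding ≈ 99.6% zeros without that fraction being targeted directly.

## Worked example

```r
library(zinbre)

pan <- generate_panel(simulation_config(horizon_hours = 2000, seed = 42))
pd  <- panel_data(as.data.frame(pan),
                  count_design = c("speed_gap", "seg_length", "lanes", "curvature"),
                  zero_design  = c("traffic_volume", "lanes"))

fit_zinb <- fit_crash_model(pd, "zinb")
fit_nb   <- fit_crash_model(pd, "nb")
fit_zinb
vuong_test(pd, fit_zinb, fit_nb)
elasticity_report(pd, fit_zinb)
```

```
Panel count model: ZINB
N = 76531 observations, 57 sites; k = 9 free parameters
                term      state estimate       se tstat   pvalue
      nb:(Intercept)      count  -9.1630 1.067000 -8.59 8.85e-18
        nb:speed_gap      count   0.0830 0.005624 14.80 2.73e-49
       nb:seg_length      count   0.3746 0.081220  4.61 3.98e-06
            nb:lanes      count   0.8008 0.264200  3.03 2.44e-03
        nb:curvature      count   0.3830 0.100500  3.81 1.39e-04
    zero:(Intercept)       zero  -3.3860 1.931000 -1.75 7.95e-02
 zero:traffic_volume       zero  -0.5201 0.117700 -4.42 1.00e-05
          zero:lanes       zero   1.2860 0.458300  2.81 5.01e-03
               alpha dispersion   3.2280 1.533000  2.11 3.52e-02
-2LL = 3227.28  AIC = 3245.28  BIC = 3328.49

Vuong test (zinb vs nb): V = 3.803  [threshold 1.96]
decision: favor_zero_inflated

       variable state       kind               method elasticity   xbar
      speed_gap count continuous          closed_form      0.219 2.6340
     seg_length count continuous          closed_form      0.349 0.9305
          lanes  both continuous observation_averaged      0.148 4.0650
      curvature count continuous          closed_form      0.321 0.8378
 traffic_volume  zero continuous observation_averaged      0.682 2.9040
```

Reading the output: each extra mph of gap between the speed limit and the
actual traffic speed (congestion) multiplies the count-state crash rate
by `exp(0.083) ≈ 1.087`; `V = 3.80 > 1.96` says the zero-inflated model
is preferred over plain NB at the 95% level; the elasticity column says a
1% increase in the speed gap raises the expected hourly crash frequency
by about 0.22%, while higher traffic volume acts through the zero state
(it makes the virtually-safe state less likely).  On this synthetic
panel those numbers echo the congestion, segment-length and curvature
effects of the reference estimates the generator draws from.

A command-line driver wraps the same pipeline
(`simulate | fit | vuong | elasticity | summarize | report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "zinbre.R", package = "zinbre"))')" \
  simulate --seed 1 --out panel.csv
```

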