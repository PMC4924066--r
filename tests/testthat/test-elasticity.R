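reference_count_state_cases <- function() {
  # count-state-only covariates: published coefficient, published sample
  # mean (continuous only) and published elasticity
  list(
    continuous = data.frame(
      variable = c("crosswind", "speed_gap", "curvature", "merge_ramps"),
      beta = c(-0.013, 0.081, 0.406, -1.072),
      xbar = c(4.147, 2.642, 0.947, 0.252),
      published = c(-0.054, 0.215, 0.385, -0.270)),
    indicator = data.frame(
      variable = c("low_speed_limit", "sunset", "november", "hour_4_5am",
                   "rutting_long"),
      beta = c(0.387, -0.200, 0.292, -0.608, 0.546),
      published = c(0.321, -0.221, 0.253, -0.836, 0.421)))
}

test_that("count-state closed forms reproduce the published elasticities", {
  cases <- reference_count_state_cases()
  cc <- cases$continuous
  # computed from the printed coefficients and means; agreement with the
  # published table is within one unit in its last printed digit, which is
  # the precision the printed inputs can support
  expect_lt(max(abs(elasticity_continuous(cc$beta, cc$xbar) -
                      cc$published)), 1e-3)
  ci <- cases$indicator
  expect_lt(max(abs(pseudo_elasticity_indicator(ci$beta) -
                      ci$published)), 1e-3)
  # frozen arithmetic of the same quantities
  expect_equal(elasticity_continuous(-0.013, 4.147), -0.053911)
  expect_equal(pseudo_elasticity_indicator(-0.608), 1 - exp(0.608))
})

test_that("closed forms have the documented analytic properties", {
  expect_identical(elasticity_continuous(0, 3.2), 0)
  expect_identical(pseudo_elasticity_indicator(0), 0)
  b <- seq(-3, 3, by = 0.25)
  pe <- pseudo_elasticity_indicator(b)
  expect_true(all(pe < 1))            # bounded above by 1
  expect_true(all(diff(pe) > 0))      # strictly increasing
  expect_true(all(sign(pe) == sign(b)))
})

fitted_elasticity_panel <- function() {
  # x continuous in the count state only; v continuous in both states;
  # d indicator in the zero state only; w indicator in the count state
  covs <- list(block = list(level = "hour", draw = function(n, ctx) {
    data.frame(x = rnorm(n, 1, 0.3), v = rlnorm(n, 0, 0.4),
               d = rbinom(n, 1, 0.4), w = rbinom(n, 1, 0.3))
  }))
  truth <- list(params = zinb_params(
    beta_nb = c(-1.5, 0.4, -0.3, 0.5),
    beta_z = c(-0.5, 0.6, 0.9),
    alpha = 0.8),
    count_design = c("x", "v", "w"), zero_design = c("v", "d"))
  cfg <- simulation_config(n_sites = 20, horizon_hours = 400,
                           retained_fraction = 1, truth = truth,
                           covariates = covs, seed = 31)
  pan <- generate_panel(cfg)
  pd <- panel_data(as.data.frame(pan), count_design = c("x", "v", "w"),
                   zero_design = c("v", "d"))
  list(data = pd, fit = fit_crash_model(pd, "zinb", se = FALSE))
}

test_that("observation-averaged elasticities reduce to closed forms and
           match a finite-difference oracle", {
  fe <- fitted_elasticity_panel()
  pd <- fe$data; fit <- fe$fit
  # count-state-only continuous covariate: exact reduction to beta * xbar
  expect_equal(elasticity_observed(pd, fit, "x"),
               elasticity_continuous(unname(fit$params$beta_nb["x"]),
                                     mean(pd$x)),
               tolerance = 1e-12)
  # count-state-only indicator: exact reduction to 1 - exp(-beta)
  expect_equal(elasticity_observed(pd, fit, "w"),
               pseudo_elasticity_indicator(unname(fit$params$beta_nb["w"])),
               tolerance = 1e-12)
  # zero-state-only indicator with beta_z > 0 lowers the expected count
  expect_lt(elasticity_observed(pd, fit, "d"), 0)
  # finite-difference oracle for the both-states continuous covariate:
  # perturb v by +/-0.1% and differentiate the model-implied mean per row
  h <- 1e-3
  e_pm <- vapply(c(1 + h, 1 - h), function(f) {
    df <- as.data.frame(pd)
    df$v <- df$v * f
    pdf <- panel_data(df, count_design = attr(pd, "count_design"),
                      zero_design = attr(pd, "zero_design"))
    lp <- linear_predictors(pdf, fit$params)
    mean(log(expected_count(lp$lambda, lp$q)))
  }, numeric(1))
  e_fd <- (e_pm[1] - e_pm[2]) / (log(1 + h) - log(1 - h))
  expect_lt(abs(elasticity_observed(pd, fit, "v") - e_fd), 1e-6)
  expect_error(elasticity_observed(pd, fit, "nope"), "neither state")
})

test_that("the elasticity report labels states, kinds and methods", {
  fe <- fitted_elasticity_panel()
  rep <- elasticity_report(fe$data, fe$fit)
  expect_setequal(rep$variable, c("x", "v", "w", "d"))
  expect_identical(rep$state[rep$variable == "x"], "count")
  expect_identical(rep$state[rep$variable == "v"], "both")
  expect_identical(rep$state[rep$variable == "d"], "zero")
  expect_identical(rep$method[rep$variable == "x"], "closed_form")
  expect_identical(rep$method[rep$variable == "v"],
                   "observation_averaged")
  expect_identical(rep$kind[rep$variable == "w"], "indicator")
  # report values agree with the individual operations
  expect_equal(rep$elasticity[rep$variable == "v"],
               elasticity_observed(fe$data, fe$fit, "v"))
  expect_equal(rep$elasticity[rep$variable == "x"],
               elasticity_continuous(unname(fe$fit$params$beta_nb["x"]),
                                     mean(fe$data$x)))
  # sign coherence for single-state variables
  expect_identical(sign(rep$elasticity[rep$variable == "x"]),
                   sign(unname(fe$fit$params$beta_nb["x"])))
  expect_identical(sign(rep$elasticity[rep$variable == "d"]),
                   -sign(unname(fe$fit$params$beta_z["d"])))
})
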