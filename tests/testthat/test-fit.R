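test_that("intercept-only Poisson reproduces the analytic MLE and SE", {
  set.seed(5)
  df <- data.frame(site_id = rep(1:5, each = 80), time_id = rep(1:80, 5),
                   count = rpois(400, 0.7))
  pd <- panel_data(df)
  fit <- fit_crash_model(pd, "poisson")
  ybar <- mean(pd$count)
  expect_equal(exp(unname(fit$params$beta_nb[1])), ybar, tolerance = 1e-8)
  # closed-form information: se(beta0) = 1/sqrt(N*ybar), so the fitted
  # rate has se sqrt(ybar/N) by the delta method
  expect_equal(unname(fit$se[1]), 1 / sqrt(400 * ybar), tolerance = 1e-4)
  expect_equal(ybar * unname(fit$se[1]), sqrt(ybar / 400),
               tolerance = 1e-4)
  expect_equal(fit$loglik, sum(dpois(pd$count, ybar, log = TRUE)),
               tolerance = 1e-10)
})

test_that("intercept-only NB recovers simulated truth and matches glm.nb", {
  set.seed(6)
  n <- 20000
  dr <- rzinb(n, lambda = 0.5, q = 0, alpha = 1.5)
  df <- data.frame(site_id = rep(1:20, each = n / 20),
                   time_id = rep(seq_len(n / 20), 20), count = dr$count)
  pd <- panel_data(df)
  fit <- fit_crash_model(pd, "nb")
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$params$beta_nb[1]) - log(0.5)),
            3 * unname(fit$se[1]))
  expect_lt(abs(fit$params$alpha - 1.5), 3 * unname(fit$se["alpha"]))
  # independent route: MASS::glm.nb in the theta = 1/alpha parameterization
  gnb <- MASS::glm.nb(count ~ 1, data = df)
  expect_equal(unname(fit$params$beta_nb[1]), unname(coef(gnb)[1]),
               tolerance = 1e-5)
  expect_equal(fit$params$alpha, 1 / gnb$theta, tolerance = 1e-4)
})

test_that("pooled zero-inflated fit matches an independent TMB-based fit", {
  pd <- vuong_panel(301, zero_inflated = TRUE)
  fit <- fit_crash_model(pd, "zinb")
  df <- as.data.frame(pd)
  g <- glmmTMB::glmmTMB(count ~ x, ziformula = ~w,
                        family = glmmTMB::nbinom2, data = df)
  expect_equal(unname(fit$params$beta_nb),
               unname(glmmTMB::fixef(g)$cond), tolerance = 1e-3)
  expect_equal(unname(fit$params$beta_z),
               unname(glmmTMB::fixef(g)$zi), tolerance = 1e-3)
  expect_equal(fit$params$alpha, 1 / glmmTMB::sigma(g), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("random-effect fit agrees with an independent TMB-based mixed
           fit on a site-heterogeneous panel", {
  # zero-inflated scenario with a count-state site effect and a handful
  # of events per site (the regime non-adaptive quadrature is built for)
  cfg <- vuong_scenario_config(77, n_sites = 40, horizon = 200)
  cfg$truth$params$beta_nb <- c(-2.5, 0.4)
  cfg$truth$params$phi_sigma <- 0.6
  pan <- generate_panel(cfg)
  pd <- panel_data(as.data.frame(pan), count_design = "x",
                   zero_design = "w")
  fit <- fit_crash_model(pd, "zinb_re",
                         config = optimizer_config(quad_order = 31))
  # the quadrature has converged at this order (well below the Laplace
  # comparison tolerances used next)
  expect_lt(abs(fit$loglik - total_loglik(pd, fit$params, 63)), 1e-4)
  df <- as.data.frame(pd)
  g <- glmmTMB::glmmTMB(count ~ x + (1 | site_id), ziformula = ~w,
                        family = glmmTMB::nbinom2, data = df)
  # Laplace (glmmTMB) vs exact Gauss-Hermite: close but not identical
  expect_lt(max(abs(fit$params$beta_nb - glmmTMB::fixef(g)$cond)), 0.02)
  phi_tmb <- sqrt(glmmTMB::VarCorr(g)$cond$site_id[1, 1])
  expect_lt(abs(fit$params$phi_sigma - phi_tmb), 0.02)
  expect_lt(abs(fit$params$alpha - 1 / glmmTMB::sigma(g)), 0.02)
  expect_lt(abs(fit$loglik - as.numeric(logLik(g))), 0.5)
  # the exact marginal likelihood is at least the Laplace approximation's
  expect_gt(fit$loglik, as.numeric(logLik(g)) - 0.01)
})

test_that("the model ladder is properly nested in log-likelihood", {
  cfg <- vuong_scenario_config(88, n_sites = 20, horizon = 300)
  cfg$truth$params$phi_sigma <- 0.5
  pan <- generate_panel(cfg)
  pd <- panel_data(as.data.frame(pan), count_design = "x",
                   zero_design = "w")
  cfgo <- fast_config()
  ll <- vapply(c("poisson", "nb", "zip", "zinb", "zinb_re"), function(m) {
    fit_crash_model(pd, m, config = cfgo, se = FALSE)$loglik
  }, numeric(1))
  tol <- 1e-4
  expect_gte(ll["nb"], ll["poisson"] - tol)
  expect_gte(ll["zinb"], ll["nb"] - tol)
  expect_gte(ll["zinb"], ll["zip"] - tol)
  expect_gte(ll["zinb_re"], ll["zinb"] - tol)
})

test_that("fits are stationary and consistent with the likelihood module", {
  pd <- vuong_panel(55, n_sites = 10, horizon = 200)
  fit <- fit_crash_model(pd, "zinb", se = FALSE)
  # reported loglik is the likelihood module's value at the estimates
  expect_equal(fit$loglik, total_loglik(pd, fit$params), tolerance = 1e-8)
  # refitting from the optimum does not move the parameters
  refit <- fit_crash_model(pd, "zinb", init = fit$theta, se = FALSE)
  expect_lt(max(abs(refit$theta - fit$theta)), 1e-5)
  # AIC/BIC identities
  ic <- information_criteria(fit)
  expect_equal(unname(ic["neg2ll"]), -2 * fit$loglik)
  expect_equal(unname(ic["aic"]), -2 * fit$loglik + 2 * fit$k)
  expect_equal(unname(ic["bic"] - ic["aic"]),
               fit$k * (log(fit$n_obs) - 2))
})

test_that("standard errors scale with information and are numerically
           stable", {
  pd <- vuong_panel(66, n_sites = 10, horizon = 200)
  fit <- fit_crash_model(pd, "zinb")
  # duplicating every site doubles the information: SEs shrink by 1/sqrt(2)
  df <- as.data.frame(pd)
  df2 <- df
  df2$site_id <- paste0(df2$site_id, "_dup")
  doubled <- panel_data(rbind(df, df2), count_design = "x",
                        zero_design = "w")
  fit2 <- fit_crash_model(doubled, "zinb", init = fit$theta)
  expect_equal(unname(fit2$se / fit$se), rep(1 / sqrt(2), length(fit$se)),
               tolerance = 1e-3)
  # halving the finite-difference step changes SEs by < 0.1%
  se_half <- standard_errors(fit, pd, step = 0.5e-4)
  expect_lt(max(abs(se_half / fit$se - 1)), 1e-3)
})

test_that("degenerate and invalid fits are handled explicitly", {
  # Poisson-generated data drives alpha to its boundary in the NB fit
  set.seed(31)
  df <- data.frame(site_id = rep(1:10, each = 600),
                   time_id = rep(1:600, 10),
                   count = rpois(6000, 0.3))
  pd <- panel_data(df)
  fit <- fit_crash_model(pd, "nb")
  expect_true("alpha" %in% fit$boundary)
  expect_true(is.na(fit$se["alpha"]))  # no fabricated boundary SE
  # random effects require repeated observations somewhere
  single <- panel_data(data.frame(site_id = 1:4, time_id = 1,
                                  count = c(0L, 1L, 0L, 2L),
                                  w = c(0, 1, 0, 1)),
                       zero_design = "w")
  expect_error(fit_crash_model(single, "zinb_re"), ">= 2 observations")
})
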