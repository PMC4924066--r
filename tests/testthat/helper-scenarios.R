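# Shared scenario builders.  All fixtures are generated in code.

# small generic panel for constructor/likelihood tests
tiny_panel <- function(seed = 42, n_sites = 3, t_i = 5) {
  set.seed(seed)
  n <- n_sites * t_i
  df <- data.frame(
    site_id = rep(letters[seq_len(n_sites)], each = t_i),
    time_id = rep(seq_len(t_i), n_sites),
    count = rpois(n, 0.6),
    x = rnorm(n),
    w = rbinom(n, 1, 0.4))
  panel_data(df, count_design = "x", zero_design = "w")
}

# a simple two-covariate scenario used for the Vuong simulations: an
# hour-varying continuous exposure x and an indicator w; zero-inflated
# (q ~ 0.5) or plain NB according to `zero_inflated`
vuong_scenario_config <- function(seed, n_sites = 40, horizon = 500,
                                  zero_inflated = TRUE) {
  covs <- list(
    x = list(level = "hour", draw = function(n, ctx) {
      data.frame(x = rnorm(n))
    }),
    w = list(level = "hour", draw = function(n, ctx) {
      data.frame(w = rbinom(n, 1, 0.3))
    }))
  truth <- if (zero_inflated) {
    list(params = zinb_params(beta_nb = c(-1.2, 0.4),
                              beta_z = c(0.3, 0.8),
                              alpha = 1, phi_sigma = 0, phi_psi = 0),
         count_design = "x", zero_design = "w")
  } else {
    list(params = zinb_params(beta_nb = c(-1.2, 0.4), beta_z = NULL,
                              alpha = 1, phi_sigma = 0, phi_psi = 0),
         count_design = "x", zero_design = character(0))
  }
  simulation_config(n_sites = n_sites, horizon_hours = horizon,
                    retained_fraction = 1, truth = truth,
                    covariates = covs, seed = seed)
}

# panels simulated for the Vuong power/size runs always carry both designs
# so that the ZINB and NB fits use identical data
vuong_panel <- function(seed, zero_inflated = TRUE, n_sites = 40,
                        horizon = 500) {
  pan <- generate_panel(vuong_scenario_config(seed, n_sites, horizon,
                                              zero_inflated))
  df <- as.data.frame(pan)
  panel_data(df, count_design = "x", zero_design = "w")
}

fast_config <- function(quad_order = 9) {
  optimizer_config(quad_order = quad_order, reltol = 1e-11)
}
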