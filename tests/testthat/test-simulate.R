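test_that("generation is deterministic and validates its configuration", {
  cfg <- simulation_config(n_sites = 6, horizon_hours = 400, seed = 99)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "truth")$structural_zero,
                   attr(p2, "truth")$structural_zero)
  expect_error(simulation_config(retained_fraction = 0), "retained_fraction")
  expect_error(simulation_config(retained_fraction = 1.2),
               "retained_fraction")
  expect_error(simulation_config(n_sites = 0), "positive")
  bad_truth <- reference_truth()
  bad_truth$params$beta_nb <- bad_truth$params$beta_nb[-2]
  expect_error(simulation_config(truth = bad_truth), "beta_nb")
})

test_that("the panel is unbalanced with site-constant geometry", {
  pan <- generate_panel(simulation_config(n_sites = 12,
                                          horizon_hours = 1200, seed = 5))
  ti <- table(pan$site_id)
  expect_gt(length(unique(as.integer(ti))), 1L)  # unbalanced
  df <- as.data.frame(pan)
  for (v in c("speed_limit", "lanes", "seg_length", "merge_ramps",
              "curvature", "rutting_life", "pavement_good")) {
    within_site <- tapply(df[[v]], df$site_id, function(z) max(z) - min(z))
    expect_equal(unname(max(within_site)), 0)
  }
  # hour-varying fields do vary within sites
  expect_gt(max(tapply(df$crosswind, df$site_id, sd)), 0)
  # derived indicators are consistent with their parents
  expect_identical(df$low_speed_limit, as.numeric(df$speed_limit < 60))
  expect_identical(df$rutting_long, as.numeric(df$rutting_life > 99))
  expect_lte(max(df$wet_surface + df$chemwet_surface), 1)  # exclusive
  # the 4-5 am hour lies inside the night window
  expect_true(all(df$night[df$hour_4_5am == 1] == 1))
})

test_that("degenerate truths behave analytically", {
  covs <- list(b = list(level = "hour", draw = function(n, ctx) {
    data.frame(x = rnorm(n))
  }))
  # a huge zero-state intercept forces q ~ 1: every count is zero
  t_allzero <- list(params = zinb_params(c(0, 0), c(50, 0), alpha = 1),
                    count_design = "x", zero_design = "x")
  pan0 <- generate_panel(simulation_config(n_sites = 5,
                                           horizon_hours = 500,
                                           retained_fraction = 1,
                                           truth = t_allzero,
                                           covariates = covs, seed = 2))
  expect_true(all(pan0$count == 0L))
  expect_true(all(attr(pan0, "truth")$structural_zero))
  # pooled Poisson truth at the study's rate: sample mean near 0.004
  t_pois <- list(params = zinb_params(c(log(0.004), 0), beta_z = NULL,
                                      alpha = 1e-12),
                 count_design = "x", zero_design = character(0))
  pan_p <- generate_panel(simulation_config(n_sites = 60,
                                            horizon_hours = 5000,
                                            retained_fraction = 1,
                                            truth = t_pois,
                                            covariates = covs, seed = 3))
  mc_se <- sqrt(0.004 / nrow(pan_p))
  expect_lt(abs(mean(pan_p$count) - 0.004), 3 * mc_se)
})

test_that("structural-zero bookkeeping matches the zero-state
           probabilities", {
  pan <- generate_panel(simulation_config(horizon_hours = 1000, seed = 17))
  # counts stay in the rare-event regime (a gross miscalibration of the
  # rate or overdispersion would blow the maximum up by orders)
  expect_lte(max(pan$count), 15)
  expect_gte(mean(pan$count == 0), 0.99)
  tr <- attr(pan, "truth")
  expect_identical(length(tr$structural_zero), nrow(pan))
  # structural-zero rows carry zero counts
  expect_true(all(pan$count[tr$structural_zero] == 0L))
  # empirical structural-zero rate matches mean(q) within 3 MC SE
  mc_se <- sqrt(mean(tr$q * (1 - tr$q)) / nrow(pan))
  expect_lt(abs(mean(tr$structural_zero) - mean(tr$q)), 3 * mc_se)
})

test_that("panel summaries are internally consistent", {
  pan <- generate_panel(simulation_config(n_sites = 8,
                                          horizon_hours = 600, seed = 8))
  sm <- summarize_panel(pan)
  expect_identical(attr(sm, "n_obs"), nrow(pan))
  expect_identical(sum(attr(sm, "t_i")), nrow(pan))
  expect_identical(attr(sm, "n_sites"), length(unique(pan$site_id)))
  # a constant column has sd 0 and min = max
  df <- as.data.frame(pan)
  df$const <- 2.5
  sm2 <- summarize_panel(panel_data(df, count_design = character(0)))
  row <- sm2[sm2$variable == "const", ]
  expect_equal(row$sd, 0)
  expect_equal(row$min, row$max)
  expect_error(summarize_panel(df[0, ]), "empty")
})
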