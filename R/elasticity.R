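#' Elasticity of expected counts for a continuous count-state covariate
#'
#' For a continuous covariate appearing only in the count state of the
#' log-linear mixture, the percent change in expected crash frequency per
#' 1% change in the covariate, evaluated at the sample mean, is
#' `beta * xbar`.
#'
#' @param beta count-state coefficient.
#' @param xbar sample mean of the covariate.
#' @return elasticity (unitless, % per %).
#' @examples
#' elasticity_continuous(-0.013, 4.147)  # cross wind in the I-25 reference
#' @export
elasticity_continuous <- function(beta, xbar) beta * xbar

#' Pseudo-elasticity of expected counts for a count-state indicator
#'
#' The relative change in expected crash frequency attributable to a 0/1
#' indicator switching on, `1 - exp(-beta)` (equivalently
#' `(exp(beta) - 1) / exp(beta)`), bounded above by 1 and increasing in
#' `beta`.
#'
#' @param beta count-state coefficient of the indicator.
#' @return pseudo-elasticity (unitless).
#' @examples
#' pseudo_elasticity_indicator(0.387)  # low speed limit indicator
#' @export
pseudo_elasticity_indicator <- function(beta) 1 - exp(-beta)

#' Observation-averaged elasticity under the fitted mixture
#'
#' Averages over observations the elasticity of the model-implied mean
#' `E(n_it) = (1 - q_it) lambda_it`.  For a continuous covariate this is
#' `mean(x_it * (beta_nb - beta_z * q_it))` with an absent-state
#' coefficient taken as 0; for an indicator it averages the relative
#' change in `E(n_it)` when the indicator toggles 0 to 1 holding the other
#' covariates fixed, `mean((E1 - E0) / E1)`, which reduces to
#' [pseudo_elasticity_indicator()] when the variable sits only in the
#' count state.  Predictors are evaluated at the population level (site
#' effects at zero).
#'
#' @param data the fitting panel.
#' @param fit a `zinb_fit`.
#' @param variable covariate name, present in either or both designs.
#' @return averaged elasticity (scalar).
#' @export
elasticity_observed <- function(data, fit, variable) {
  in_nb <- variable %in% fit$count_design
  in_z <- fit$spec$has_z && variable %in% fit$zero_design
  if (!in_nb && !in_z) {
    stop("variable '", variable, "' is in neither state design",
         call. = FALSE)
  }
  x <- as.data.frame(data)[[variable]]
  indicator <- all(x %in% c(0, 1))
  p <- fit$params
  lp <- linear_predictors(data, p)
  b_nb <- if (in_nb) unname(p$beta_nb[variable]) else 0
  b_z <- if (in_z) unname(p$beta_z[variable]) else 0
  if (!indicator) {
    return(mean(x * (b_nb - b_z * lp$q)))
  }
  # toggle the indicator 0 -> 1 holding everything else fixed
  eta <- log(lp$lambda) - b_nb * x
  zeta <- stats::qlogis(lp$q) - b_z * x
  e0 <- (1 - stats::plogis(zeta)) * exp(eta)
  e1 <- (1 - stats::plogis(zeta + b_z)) * exp(eta + b_nb)
  mean((e1 - e0) / e1)
}

#' Elasticity report for a fitted model
#'
#' One record per covariate: its state membership, kind (continuous or
#' indicator), the method used and the value.  Covariates appearing in
#' exactly one state and only the count state use the mean-evaluated
#' closed forms ([elasticity_continuous()], the sample mean taken from
#' `data`, or [pseudo_elasticity_indicator()]); covariates in the zero
#' state or in both states use the observation-averaged method, whose
#' value depends on the observation-level distribution of `q_it`.
#'
#' @param data the fitting panel.
#' @param fit a `zinb_fit`.
#' @param variables covariates to report (default: all in either design).
#' @return data.frame of class `elasticity_report` with columns `variable`,
#'   `state`, `kind`, `method`, `elasticity`, `xbar`.
#' @export
elasticity_report <- function(data, fit, variables = NULL) {
  all_vars <- union(fit$count_design,
                    if (fit$spec$has_z) fit$zero_design else character(0))
  if (is.null(variables)) variables <- all_vars
  bad <- setdiff(variables, all_vars)
  if (length(bad) > 0L) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(data)
  rows <- lapply(variables, function(v) {
    in_nb <- v %in% fit$count_design
    in_z <- fit$spec$has_z && v %in% fit$zero_design
    state <- if (in_nb && in_z) "both" else if (in_nb) "count" else "zero"
    kind <- if (all(df[[v]] %in% c(0, 1))) "indicator" else "continuous"
    xbar <- mean(df[[v]])
    if (state == "count") {
      val <- if (kind == "continuous") {
        elasticity_continuous(unname(fit$params$beta_nb[v]), xbar)
      } else {
        pseudo_elasticity_indicator(unname(fit$params$beta_nb[v]))
      }
      method <- "closed_form"
    } else {
      val <- elasticity_observed(data, fit, v)
      method <- "observation_averaged"
    }
    data.frame(variable = v, state = state, kind = kind, method = method,
               elasticity = val, xbar = xbar)
  })
  structure(do.call(rbind, rows),
            class = c("elasticity_report", "data.frame"))
}

#' @export
print.elasticity_report <- function(x, digits = 3, ...) {
  cat("Elasticities of expected crash frequency (% per %, indicators:",
      "relative change)\n")
  print.data.frame(transform(x, elasticity = round(elasticity, digits),
                             xbar = signif(xbar, 4)), row.names = FALSE)
  invisible(x)
}

#' Published estimates of the I-25 reference study
#'
#' The fitted random-effect zero-inflated negative binomial coefficients
#' and t-statistics, fit statistics, and covariate summary moments of the
#' hourly I-25 Colorado crash panel (57 segments, 328,529 segment-hours,
#' 1,352 crashes) that this package's synthetic generator is calibrated
#' to.  These printed values parameterize the default simulation truth and
#' the worked elasticity examples; they are transcribed constants, not
#' outputs of this package.
#'
#' @return list with `coefficients` (variable, state, estimate, tstat),
#'   `summary` (variable, mean, sd, min, max, kind, level), and `stats`
#'   (alpha, phi_sigma, vuong, neg2ll, aic, bic, n_obs, n_sites).
#' @export
i25_reference <- function() {
  coefficients <- data.frame(
    variable = c("constant", "visibility", "wet_surface", "chemwet_surface",
                 "traffic_volume", "truck_pct", "night", "seg_length",
                 "lanes", "pavement_good",
                 "constant", "crosswind", "wet_surface", "low_speed_limit",
                 "speed_gap", "truck_pct", "sunset", "november",
                 "hour_4_5am", "merge_ramps", "seg_length", "lanes",
                 "curvature", "rutting_long"),
    state = c(rep("zero", 10), rep("count", 14)),
    estimate = c(-10.731, 0.959, -1.663, -1.864, -0.611, 0.439, 0.352,
                 0.755, 1.917, 0.680,
                 -10.673, -0.013, -0.529, 0.387, 0.081, 0.107, -0.200,
                 0.292, -0.608, -1.072, 0.786, 0.849, 0.406, 0.546),
    tstat = c(-5.84, 1.78, -3.64, -5.04, -9.06, 5.95, 1.94, 4.60, 6.10,
              2.63,
              -9.31, -1.75, -3.70, 1.83, 29.75, 2.69, -1.88, 3.20, -1.96,
              -2.65, 5.44, 3.69, 3.07, 2.88))
  summary <- data.frame(
    variable = c("crash_count", "wet_surface", "chemwet_surface",
                 "visibility", "crosswind", "precip_rate", "temperature",
                 "speed_limit", "speed_gap", "traffic_volume", "truck_pct",
                 "night", "sunset", "november", "hour_4_5am", "merge_ramps",
                 "seg_length", "lanes", "rutting_life", "curvature",
                 "pavement_good", "median_width", "shoulder_out",
                 "shoulder_in", "grade"),
    mean = c(0.004, 0.082, 0.037, 1.075, 4.147, 0.021, 57.016, 61.027,
             2.642, 2.916, 6.215, 0.431, 0.062, 0.095, 0.040, 0.252,
             1.014, 4.159, 97.013, 0.947, 0.419, 13.812, 10.335, 9.006,
             -0.018),
    sd = c(0.066, 0.275, 0.188, 0.136, 3.906, 0.443, 24.473, 5.327, 5.533,
           2.101, 1.922, 0.495, 0.241, 0.294, 0.196, 0.215, 0.769, 0.562,
           2.984, 0.681, 0.493, 28.604, 2.181, 2.583, 1.206),
    min = c(0, 0, 0, 0, 0, 0, -1.333, 55, 0, 0.030, 2.8, 0, 0, 0, 0, 0,
            0.236, 3, 86, 0, 0, 4, 6, 5, -2.334),
    max = c(4, 1, 1, 1.1, 31.98, 32, 159, 75, 69.18, 14.988, 10.7, 1, 1,
            1, 1, 0.926, 4.5, 5, 100, 2.26, 1, 183, 15, 15, 2.334),
    kind = c("count", "indicator", "indicator", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "indicator", "indicator",
             "indicator", "indicator", "continuous", "continuous",
             "discrete", "continuous", "continuous", "indicator",
             "continuous", "continuous", "continuous", "continuous"),
    level = c("hour", "hour", "hour", "hour", "hour", "hour", "hour",
              "site", "hour", "hour", "hour", "hour", "hour", "hour",
              "hour", "site", "site", "site", "site", "site", "site",
              "site", "site", "site", "site"))
  stats <- list(alpha = 1.818, alpha_tstat = 3.57, phi_sigma = 0.484,
                phi_sigma_tstat = 7.54, vuong = 4.48, neg2ll = 15145,
                aic = 15197, bic = 15250, n_obs = 328529, n_sites = 57,
                n_crashes = 1352, zero_fraction = 0.996)
  list(coefficients = coefficients, summary = summary, stats = stats)
}
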