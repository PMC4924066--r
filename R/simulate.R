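# Synthetic unbalanced hourly segment-panel generator.
#
# Emulates the structure of the hourly I-25 crash panel: 57 road segments
# observed over up to 365 x 24 hours with station-outage missingness
# (expected retained fraction 328,529 / (57 * 8760) ~ 0.658), covariates
# matching the published summary moments, and counts drawn forward from
# the random-effects ZINB with the published estimates as the default
# truth, which yields ~99.6% zeros and single-digit maxima.

truncnorm_cache <- new.env(parent = emptyenv())

# underlying normal parameters whose (lo, hi)-truncated moments match the
# target mean/sd; solved once per target and memoized
truncnorm_solve <- function(mean, sd, lo, hi) {
  key <- paste(mean, sd, lo, hi, sep = "|")
  if (!is.null(truncnorm_cache[[key]])) return(truncnorm_cache[[key]])
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / Z
    v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    if (any(!is.finite(mm))) return(1e6)
    sum(((mm - c(mean, sd)) / sd)^2)
  }
  sol <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- list(mu = sol$par[1], sigma = exp(sol$par[2]))
  truncnorm_cache[[key]] <- out
  out
}

rtruncnorm_m <- function(n, mean, sd, lo, hi) {
  p <- truncnorm_solve(mean, sd, lo, hi)
  u <- stats::runif(n, stats::pnorm((lo - p$mu) / p$sigma),
                    stats::pnorm((hi - p$mu) / p$sigma))
  p$mu + p$sigma * stats::qnorm(u)
}

#' Default generating truth: the published reference estimates
#'
#' The count- and zero-state designs and coefficient values of the
#' reference random-effect ZINB fit ([i25_reference()]), overdispersion
#' 1.818 and count-state site-effect standard deviation 0.484.  Covariates
#' outside these designs are still generated but carry zero coefficients.
#'
#' @return list with `params` ([zinb_params()]), `count_design`,
#'   `zero_design`.
#' @export
reference_truth <- function() {
  ref <- i25_reference()$coefficients
  cs <- ref[ref$state == "count", ]
  zs <- ref[ref$state == "zero", ]
  count_design <- setdiff(cs$variable, "constant")
  zero_design <- setdiff(zs$variable, "constant")
  list(
    params = zinb_params(
      beta_nb = stats::setNames(cs$estimate,
                                c("(Intercept)", count_design)),
      beta_z = stats::setNames(zs$estimate, c("(Intercept)", zero_design)),
      alpha = i25_reference()$stats$alpha,
      phi_sigma = i25_reference()$stats$phi_sigma,
      phi_psi = 0),
    count_design = count_design,
    zero_design = zero_design)
}

#' Default covariate models of the reference scenario
#'
#' A list of draw blocks reproducing the published covariate moments.
#' Site-constant geometry (speed limit, lanes, segment length, ramps,
#' curvature, rutting, pavement, medians, shoulders, grade) is drawn once
#' per site; temporal indicators come from a deterministic hour-of-day
#' calendar (night 20:00-05:59, a sunset window around 18:00-19:59, the
#' 4-5 am hour) with November days shared across sites; weather and
#' traffic are drawn per segment-hour.  Continuous covariates use
#' moment-matched truncated normals at the published min-max, traffic
#' volume a lognormal, visibility a clear/fog-event mixture and the
#' speed-limit-minus-speed gap a free-flow/congestion mixture.  Variables
#' are independent across blocks apart from deterministic exclusions (wet
#' and chemically-wet surface are mutually exclusive; the indicators
#' derive from their parent variables).
#'
#' @return named list of blocks, each `list(level, draw)` with level
#'   `"site"`, `"day"` or `"hour"`; `draw(n, ctx)` returns a vector or
#'   data.frame (`ctx$time_id` holds the hour index for hour blocks).
#' @export
reference_covariate_models <- function() {
  list(
    geometry = list(level = "site", draw = function(n, ctx) {
      speed_limit <- sample(c(55, 60, 65, 75), n, replace = TRUE,
                            prob = c(0.32, 0.34, 0.24, 0.10))
      rutting_life <- rtruncnorm_m(n, 97.013, 2.984, 86, 100)
      data.frame(
        speed_limit = speed_limit,
        low_speed_limit = as.numeric(speed_limit < 60),
        lanes = sample(c(3, 4, 5), n, replace = TRUE,
                       prob = c(0.10, 0.64, 0.26)),
        seg_length = rtruncnorm_m(n, 1.014, 0.769, 0.236, 4.5),
        merge_ramps = rtruncnorm_m(n, 0.252, 0.215, 0, 0.926),
        curvature = rtruncnorm_m(n, 0.947, 0.681, 0, 2.26),
        rutting_life = rutting_life,
        rutting_long = as.numeric(rutting_life > 99),
        pavement_good = stats::rbinom(n, 1, 0.419),
        # barrier-separated narrow medians vs occasional wide depressed
        # medians; a two-point-style mixture reaches the heavy right skew
        # (mean 13.8, sd 28.6) that a truncated normal cannot
        median_width = ifelse(stats::runif(n) < 0.0685,
                              stats::runif(n, 100, 140),
                              stats::runif(n, 4, 8)),
        shoulder_out = rtruncnorm_m(n, 10.335, 2.181, 6, 15),
        shoulder_in = rtruncnorm_m(n, 9.006, 2.583, 5, 15),
        grade = rtruncnorm_m(n, -0.018, 1.206, -2.334, 2.334))
    }),
    november = list(level = "day", draw = function(n, ctx) {
      data.frame(november = stats::rbinom(n, 1, 0.095))
    }),
    calendar = list(level = "hour", draw = function(n, ctx) {
      hod <- ctx$time_id %% 24
      day <- ctx$time_id %/% 24
      data.frame(
        night = as.numeric(hod >= 20 | hod <= 5),
        sunset = as.numeric(hod == 19 | (hod == 18 & day %% 2 == 0)),
        hour_4_5am = as.numeric(hod == 4))
    }),
    weather = list(level = "hour", draw = function(n, ctx) {
      fog <- stats::runif(n) < 0.0385
      visibility <- rep(1.1, n)
      visibility[fog] <- stats::runif(sum(fog), 0, 0.9)
      surf <- stats::runif(n)
      rain <- stats::runif(n) < 0.01018
      precip <- numeric(n)
      precip[rain] <- pmin(stats::rlnorm(sum(rain), -0.004, sqrt(1.492)), 32)
      data.frame(
        visibility = visibility,
        crosswind = rtruncnorm_m(n, 4.147, 3.906, 0, 31.98),
        wet_surface = as.numeric(surf < 0.082),
        chemwet_surface = as.numeric(surf >= 0.082 & surf < 0.119),
        precip_rate = precip,
        temperature = rtruncnorm_m(n, 57.016, 24.473, -1.333, 159))
    }),
    traffic = list(level = "hour", draw = function(n, ctx) {
      congested <- stats::runif(n) < 0.13
      gap <- stats::rexp(n, rate = 1 / 0.8)
      gap[congested] <- pmin(stats::rgamma(sum(congested), shape = 3.52,
                                           scale = 4.26), 69.18)
      data.frame(
        speed_gap = pmin(gap, 69.18),
        traffic_volume = pmin(pmax(stats::rlnorm(n, 0.861, 0.6466), 0.03),
                              14.988),
        truck_pct = rtruncnorm_m(n, 6.215, 1.922, 2.8, 10.7))
    })
  )
}

#' Simulation configuration for the synthetic panel generator
#'
#' @param n_sites number of road segments (default 57).
#' @param horizon_hours hours per site before missingness (default
#'   365 * 24 = 8760).
#' @param retained_fraction expected fraction of segment-hours surviving
#'   the station-outage missingness (default 0.658); outages are MCAR
#'   random blocks per site, so the realized `t_i` differ across sites.
#' @param truth generating parameters and designs, as [reference_truth()].
#' @param covariates covariate draw blocks, as
#'   [reference_covariate_models()].
#' @param seed integer seed; the panel is byte-reproducible from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 57, horizon_hours = 8760,
                              retained_fraction = 0.658,
                              truth = reference_truth(),
                              covariates = reference_covariate_models(),
                              seed = 1) {
  if (n_sites < 1 || horizon_hours < 1) {
    stop("n_sites and horizon_hours must be positive", call. = FALSE)
  }
  if (retained_fraction <= 0 || retained_fraction > 1) {
    stop("retained_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!inherits(truth$params, "zinb_params")) {
    stop("truth$params must be a zinb_params object", call. = FALSE)
  }
  if (length(truth$params$beta_nb) != length(truth$count_design) + 1L) {
    stop("truth beta_nb length does not match count_design", call. = FALSE)
  }
  if (!is.null(truth$params$beta_z) &&
      length(truth$params$beta_z) != length(truth$zero_design) + 1L) {
    stop("truth beta_z length does not match zero_design", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites),
                 horizon_hours = as.integer(horizon_hours),
                 retained_fraction = retained_fraction,
                 truth = truth, covariates = covariates,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic unbalanced hourly segment panel
#'
#' Draws site effects `sigma_i ~ N(0, phi_sigma^2)` and
#' `psi_i ~ N(0, phi_psi^2)`, covariates per the configured blocks, then
#' for each segment-hour a structural zero with probability `q_it` or a
#' negative binomial count via its gamma-mixed Poisson representation, and
#' finally removes per-site random outage blocks.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_panel`: a [panel_data()] with the truth designs
#'   attached, plus attribute `truth` (generating parameters, drawn site
#'   effects, per-row latent structural-zero state, dropped-hour count).
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  set.seed(config$seed)
  I <- config$n_sites
  H <- config$horizon_hours
  site_ids <- sprintf("S%02d", seq_len(I))
  grid_site <- rep(seq_len(I), each = H)
  grid_time <- rep.int(seq_len(H) - 1L, I)
  n <- I * H
  truth <- config$truth
  p <- truth$params

  sigma_i <- stats::rnorm(I, 0, p$phi_sigma)
  psi_i <- stats::rnorm(I, 0, p$phi_psi)

  cols <- list()
  n_days <- (H + 23L) %/% 24L
  for (blk in config$covariates) {
    val <- switch(blk$level,
      site = {
        v <- blk$draw(I, list())
        as.data.frame(v)[grid_site, , drop = FALSE]
      },
      day = {
        v <- as.data.frame(blk$draw(n_days, list()))
        v[(grid_time %/% 24L) + 1L, , drop = FALSE]
      },
      hour = as.data.frame(blk$draw(n, list(time_id = grid_time))),
      stop("unknown covariate level: ", blk$level, call. = FALSE))
    rownames(val) <- NULL
    cols[[length(cols) + 1L]] <- val
  }
  covs <- do.call(cbind, cols)
  missing_vars <- setdiff(union(truth$count_design, truth$zero_design),
                          names(covs))
  if (length(missing_vars) > 0L) {
    stop("covariate blocks do not produce design variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }

  X <- cbind(1, as.matrix(covs[truth$count_design]))
  eta <- drop(X %*% p$beta_nb) + sigma_i[grid_site]
  lambda <- exp(pmin(eta, 30))
  if (!is.null(p$beta_z)) {
    Z <- cbind(1, as.matrix(covs[truth$zero_design]))
    q <- stats::plogis(drop(Z %*% p$beta_z) + psi_i[grid_site])
  } else {
    q <- rep(0, n)
  }
  structural <- stats::runif(n) < q
  rate <- lambda
  if (p$alpha > 1e-8) {
    rate <- lambda * stats::rgamma(n, shape = 1 / p$alpha, scale = p$alpha)
  }
  count <- stats::rpois(n, rate)
  count[structural] <- 0L

  # station outages: per site, Poisson(6) blocks with exponential lengths
  # chosen so that the expected uncovered fraction is retained_fraction
  keep <- rep(TRUE, n)
  if (config$retained_fraction < 1) {
    mean_len <- H * (-log(config$retained_fraction)) / 6
    for (i in seq_len(I)) {
      k <- stats::rpois(1, 6)
      if (k == 0) next
      start <- stats::runif(k, 0, H)
      len <- stats::rexp(k, rate = 1 / mean_len)
      off <- rep(FALSE, H)
      for (j in seq_len(k)) {
        idx <- seq.int(floor(start[j]) + 1L,
                       min(H, floor(start[j] + len[j]) + 1L))
        off[idx] <- TRUE
      }
      if (sum(!off) < 24L) off[seq_len(24L)] <- FALSE  # keep sites observed
      keep[(i - 1L) * H + which(off)] <- FALSE
    }
  }

  df <- cbind(data.frame(site_id = site_ids[grid_site[keep]],
                         time_id = grid_time[keep],
                         count = as.integer(count[keep])),
              covs[keep, , drop = FALSE])
  rownames(df) <- NULL
  pd <- panel_data(df, count_design = truth$count_design,
                   zero_design = truth$zero_design)
  attr(pd, "truth") <- list(
    params = p, sigma_i = stats::setNames(sigma_i, site_ids),
    psi_i = stats::setNames(psi_i, site_ids),
    structural_zero = structural[keep],
    q = q[keep], lambda = lambda[keep],
    n_dropped = sum(!keep), seed = config$seed)
  class(pd) <- c("simulated_panel", class(pd))
  pd
}
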