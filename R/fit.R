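#' Optimizer configuration
#'
#' @param max_iter maximum BFGS iterations per stage.
#' @param reltol relative convergence tolerance of the objective.
#' @param grad_tol gradient max-norm below which a fit is declared
#'   stationary (scaled by `1 + |loglik|`).
#' @param fd_step relative central-difference step for the numerical
#'   Hessian used for standard errors.
#' @param quad_order Gauss-Hermite order per random dimension.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_iter = 400, reltol = 1e-12,
                             grad_tol = 1e-4, fd_step = 1e-4,
                             quad_order = 15) {
  stopifnot(max_iter >= 1, reltol > 0, grad_tol > 0, fd_step > 0,
            quad_order >= 1)
  structure(list(max_iter = max_iter, reltol = reltol, grad_tol = grad_tol,
                 fd_step = fd_step, quad_order = quad_order),
            class = "optimizer_config")
}

# internal model descriptor per label
model_spec <- function(model, random) {
  switch(model,
    poisson = list(pois = TRUE, has_z = FALSE, re_sigma = FALSE,
                   re_psi = FALSE),
    nb = list(pois = FALSE, has_z = FALSE, re_sigma = FALSE, re_psi = FALSE),
    zip = list(pois = TRUE, has_z = TRUE, re_sigma = FALSE, re_psi = FALSE),
    zinb = list(pois = FALSE, has_z = TRUE, re_sigma = FALSE,
                re_psi = FALSE),
    zinb_re = list(pois = FALSE, has_z = TRUE,
                   re_sigma = random %in% c("sigma", "both"),
                   re_psi = random %in% c("psi", "both")),
    stop("unknown model label: ", model, call. = FALSE))
}

# theta layout: beta_nb | [beta_z] | [log alpha] | [log phi_s] | [log phi_p]
theta_layout <- function(spec, pc, pz) {
  nm <- paste0("nb.", seq_len(pc))
  if (spec$has_z) nm <- c(nm, paste0("z.", seq_len(pz)))
  if (!spec$pois) nm <- c(nm, "log_alpha")
  if (spec$re_sigma) nm <- c(nm, "log_phi_sigma")
  if (spec$re_psi) nm <- c(nm, "log_phi_psi")
  nm
}

theta_unpack <- function(theta, spec, pc, pz) {
  out <- list(beta_nb = theta[seq_len(pc)], beta_z = NULL,
              alpha = 1e-12, phi_sigma = 0, phi_psi = 0)
  pos <- pc
  if (spec$has_z) {
    out$beta_z <- theta[pos + seq_len(pz)]
    pos <- pos + pz
  }
  # clamp the log-scale transforms so optimizer line-search excursions
  # cannot overflow 1/alpha or the quadrature scale
  if (!spec$pois) {
    out$alpha <- exp(min(max(theta[pos + 1L], -25), 25)); pos <- pos + 1L
  }
  if (spec$re_sigma) {
    out$phi_sigma <- exp(min(max(theta[pos + 1L], -25), 10)); pos <- pos + 1L
  }
  if (spec$re_psi) {
    out$phi_psi <- exp(min(max(theta[pos + 1L], -25), 10)); pos <- pos + 1L
  }
  out
}

# negative loglik and gradient closure with one-step memoization
make_objective <- function(y, X, Z, site, n_site, spec, quad_order) {
  pc <- ncol(X); pz <- if (spec$has_z) ncol(Z) else 0L
  pre <- ll_pre(y)
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) {
      return(cache$val)
    }
    pars <- theta_unpack(theta, spec, pc, pz)
    res <- ll_eval(y, X, Z, site, n_site, pars$beta_nb, pars$beta_z,
                   pars$alpha, pars$phi_sigma, pars$phi_psi,
                   quad_order, spec, want_grad = TRUE, pre = pre)
    val <- list(nll = -res$loglik, grad = -unlist(res$grad, use.names = FALSE))
    cache$theta <- theta
    cache$val <- val
    val
  }
  list(
    fn = function(theta) evaluate(theta)$nll,
    gr = function(theta) evaluate(theta)$grad,
    loglik_only = function(theta) {
      pars <- theta_unpack(theta, spec, pc, pz)
      ll_eval(y, X, Z, site, n_site, pars$beta_nb, pars$beta_z, pars$alpha,
              pars$phi_sigma, pars$phi_psi, quad_order, spec, pre = pre)$loglik
    }
  )
}

# boundary detection on the internal scale: a log-scale parameter that has
# drifted below its natural-scale threshold is a boundary fit (alpha -> 0
# or phi -> 0), reported at the boundary rather than as an interior optimum
theta_boundary <- function(theta) {
  nm <- names(theta)
  (nm == "log_alpha" & theta < log(1e-5)) |
    (nm %in% c("log_phi_sigma", "log_phi_psi") & theta < log(1e-3))
}

run_optim <- function(init, obj, config) {
  stats::optim(init, obj$fn, obj$gr, method = "BFGS",
               control = list(maxit = config$max_iter,
                              reltol = config$reltol))
}

# staged initial values; each stage starts from the previous fitted model
staged_init <- function(y, X, Z, site, n_site, model, random, quad_order,
                        config) {
  mean_y <- mean(y)
  b0 <- c(log(max(mean_y, 1e-8)), numeric(ncol(X) - 1L))
  if (model == "poisson") return(b0)
  run <- function(m, init) {
    sp <- model_spec(m, random)
    obj <- make_objective(y, X, Z, site, n_site, sp, quad_order)
    run_optim(init, obj, config)$par
  }
  th_p <- run("poisson", b0)
  lam <- exp(pmin(drop(X %*% th_p), 30))
  if (model %in% c("nb", "zinb", "zinb_re")) {
    # method-of-moments overdispersion from Pearson-type residuals
    a0 <- max((sum((y - lam)^2) - sum(lam)) / sum(lam^2), 0.02)
    th_nb <- run("nb", c(th_p, log(a0)))
    if (model == "nb") return(th_nb)
    # zero-state intercept from the excess-zero fraction
    a_hat <- exp(th_nb[length(th_nb)])
    lam_nb <- exp(pmin(drop(X %*% th_nb[seq_len(ncol(X))]), 30))
    p0 <- mean((1 + a_hat * lam_nb)^(-1 / a_hat))
    q0 <- min(max((mean(y == 0) - p0) / max(1 - p0, 1e-6), 0.02), 0.9)
    bnb <- th_nb[seq_len(ncol(X))]
    bnb[1L] <- bnb[1L] - log(1 - q0)
    bz <- c(stats::qlogis(q0), numeric(ncol(Z) - 1L))
    th_zinb <- run("zinb", c(bnb, bz, th_nb[length(th_nb)]))
    if (model == "zinb") return(th_zinb)
    # phi from the spread of site-level observed/expected log ratios
    sp <- model_spec("zinb", random)
    pars <- theta_unpack(th_zinb, sp, ncol(X), ncol(Z))
    lamz <- exp(pmin(drop(X %*% pars$beta_nb), 30))
    qz <- stats::plogis(drop(Z %*% pars$beta_z))
    eit <- (1 - qz) * lamz
    O <- rowsum_vec(as.numeric(y), site, n_site)
    E <- rowsum_vec(eit, site, n_site)
    phi0 <- min(max(stats::sd(log((O + 0.5) / (E + 0.5))), 0.1), 2)
    extra <- c(if (random %in% c("sigma", "both")) log(phi0),
               if (random %in% c("psi", "both")) log(phi0))
    return(c(th_zinb, extra))
  }
  if (model == "zip") {
    p0 <- mean(exp(-lam))
    q0 <- min(max((mean(y == 0) - p0) / max(1 - p0, 1e-6), 0.02), 0.9)
    bnb <- th_p
    bnb[1L] <- bnb[1L] - log(1 - q0)
    return(c(bnb, stats::qlogis(q0), numeric(ncol(Z) - 1L)))
  }
  stop("unknown model label: ", model, call. = FALSE)
}

#' Fit a panel count model by maximum (marginal) likelihood
#'
#' Estimates one of the model ladder `poisson`, `nb`, `zip`, `zinb`,
#' `zinb_re` on an unbalanced panel.  Positive parameters are estimated on
#' the log scale (`log alpha`, `log phi`), so positivity is guaranteed;
#' estimates and standard errors are reported on the natural scale via the
#' delta method.  Initialization is staged through the ladder: Poisson
#' slopes seed the NB fit, the NB fit and the excess-zero fraction seed the
#' zero-inflated fits, and the spread of site-level observed/expected
#' ratios seeds the random-effect scale.  Random effects are integrated
#' out by Gauss-Hermite quadrature of order `config$quad_order`.
#'
#' @param data a [panel_data()] with non-empty designs as required.
#' @param model model label.
#' @param random which states carry a site effect for `zinb_re`:
#'   `"sigma"` (count state, default), `"psi"` (zero state) or `"both"`.
#' @param config an [optimizer_config()].
#' @param init optional explicit start vector on the internal scale
#'   (bypasses staged initialization).
#' @param se compute the observed-information standard errors (can be
#'   disabled for speed in simulation loops).
#' @return object of class `zinb_fit`: coefficient table, [zinb_params()]
#'   estimates, log-likelihood, AIC/BIC, convergence diagnostics.
#' @examples
#' set.seed(1)
#' df <- data.frame(site_id = rep(1:4, each = 50), time_id = rep(1:50, 4),
#'                  count = rpois(200, 0.3), x = rnorm(200))
#' pd <- panel_data(df, count_design = "x")
#' fit <- fit_crash_model(pd, "poisson")
#' coef(fit)
#' @export
fit_crash_model <- function(data, model = c("poisson", "nb", "zip", "zinb",
                                            "zinb_re"),
                            random = c("sigma", "psi", "both"),
                            config = optimizer_config(), init = NULL,
                            se = TRUE) {
  model <- match.arg(model)
  random <- match.arg(random)
  spec <- model_spec(model, random)
  y <- data$count
  X <- panel_design(data, "count")
  Z <- if (spec$has_z) panel_design(data, "zero")
  sites <- unique(data$site_id)
  site <- match(data$site_id, sites)
  n_site <- length(sites)
  if (model == "zinb_re" && max(tabulate(site)) < 2L) {
    stop("random effects need at least one site with >= 2 observations",
         call. = FALSE)
  }
  obj <- make_objective(y, X, Z, site, n_site, spec, config$quad_order)
  if (is.null(init)) {
    init <- staged_init(y, X, Z, site, n_site, model, random,
                        config$quad_order, config)
  }
  pc <- ncol(X); pz <- if (spec$has_z) ncol(Z) else 0L
  opt <- run_optim(init, obj, config)
  gnorm <- max(abs(obj$gr(opt$par)))
  if (gnorm > config$grad_tol * (1 + abs(opt$value))) {  # one polish pass
    opt2 <- run_optim(opt$par, obj, config)
    if (opt2$value <= opt$value) opt <- opt2
    gnorm <- max(abs(obj$gr(opt$par)))
  }
  theta <- opt$par
  names(theta) <- theta_layout(spec, pc, pz)
  pars <- theta_unpack(theta, spec, pc, pz)
  params <- zinb_params(
    beta_nb = stats::setNames(pars$beta_nb, colnames(X)),
    beta_z = if (spec$has_z) stats::setNames(pars$beta_z, colnames(Z)),
    alpha = if (spec$pois) 1e-12 else pars$alpha,
    phi_sigma = pars$phi_sigma, phi_psi = pars$phi_psi)
  loglik <- -opt$value
  k <- length(theta)
  n <- length(y)
  boundary <- character(0)
  if (!spec$pois && pars$alpha < 1e-5) boundary <- c(boundary, "alpha")
  if (spec$re_sigma && pars$phi_sigma < 1e-3) {
    boundary <- c(boundary, "phi_sigma")
  }
  if (spec$re_psi && pars$phi_psi < 1e-3) boundary <- c(boundary, "phi_psi")
  fit <- structure(list(
    model = model, random = if (model == "zinb_re") random else "none",
    theta = theta, params = params, spec = spec,
    loglik = loglik, neg2ll = -2 * loglik,
    aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n),
    k = k, n_obs = n, n_sites = n_site,
    quad_order = config$quad_order, config = config,
    count_design = attr(data, "count_design"),
    zero_design = attr(data, "zero_design"),
    converged = opt$convergence == 0L, grad_norm = gnorm,
    optim_counts = opt$counts, boundary = boundary,
    se = NULL, vcov = NULL, coefficients = NULL
  ), class = "zinb_fit")
  if (se) fit <- add_standard_errors(fit, data)
  fit$coefficients <- coef_table(fit)
  fit
}

# observed information on the internal scale by central differences of the
# analytic gradient; delta method to the natural scale
add_standard_errors <- function(fit, data, step = NULL) {
  spec <- fit$spec
  y <- data$count
  X <- panel_design(data, "count")
  Z <- if (spec$has_z) panel_design(data, "zero")
  sites <- unique(data$site_id)
  site <- match(data$site_id, sites)
  obj <- make_objective(y, X, Z, site, length(sites), spec, fit$quad_order)
  theta <- fit$theta
  p <- length(theta)
  if (is.null(step)) step <- fit$config$fd_step
  # boundary parameters (alpha or phi collapsed to zero) are not interior
  # maximizers: they are profiled out of the information matrix and
  # reported without a standard error rather than with a fabricated one
  free <- which(!theta_boundary(theta))
  H <- matrix(0, length(free), length(free))
  for (jj in seq_along(free)) {
    j <- free[jj]
    h <- step * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, jj] <- ((obj$gr(tp) - obj$gr(tm)) / (2 * h))[free]
  }
  H <- (H + t(H)) / 2
  vcov_f <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(vcov_f) || any(diag(vcov_f) <= 0)
  if (singular) {
    warning("observed information is not positive definite; ",
            "pseudo-inverse standard errors are flagged", call. = FALSE)
    vcov_f <- MASS::ginv(H)
  }
  vcov <- matrix(NA_real_, p, p)
  vcov[free, free] <- vcov_f
  se_int <- sqrt(pmax(diag(vcov), 0))
  # delta method: d exp(t) / dt = exp(t) for the log-scale parameters
  jac <- rep(1, p)
  logpars <- grepl("^log_", names(theta))
  jac[logpars] <- exp(theta[logpars])
  fit$vcov <- vcov
  fit$se <- stats::setNames(se_int * jac, natural_names(names(theta), fit))
  fit$se_flagged <- singular
  fit
}

natural_names <- function(nm, fit) {
  cn <- c("(Intercept)", fit$count_design)
  zn <- c("(Intercept)", fit$zero_design)
  out <- nm
  out[grepl("^nb\\.", nm)] <- paste0("nb:", cn)
  if (fit$spec$has_z) out[grepl("^z\\.", nm)] <- paste0("zero:", zn)
  out[nm == "log_alpha"] <- "alpha"
  out[nm == "log_phi_sigma"] <- "phi_sigma"
  out[nm == "log_phi_psi"] <- "phi_psi"
  out
}

coef_table <- function(fit) {
  est <- c(fit$params$beta_nb,
           if (fit$spec$has_z) fit$params$beta_z,
           if (!fit$spec$pois) fit$params$alpha,
           if (fit$spec$re_sigma) fit$params$phi_sigma,
           if (fit$spec$re_psi) fit$params$phi_psi)
  nm <- natural_names(names(fit$theta), fit)
  state <- c(rep("count", length(fit$params$beta_nb)),
             if (fit$spec$has_z) rep("zero", length(fit$params$beta_z)),
             if (!fit$spec$pois) "dispersion",
             if (fit$spec$re_sigma) "random", if (fit$spec$re_psi) "random")
  se <- if (!is.null(fit$se)) unname(fit$se) else rep(NA_real_, length(est))
  tstat <- unname(est) / se
  data.frame(term = nm, state = state, estimate = unname(est), se = se,
             tstat = tstat, pvalue = 2 * stats::pnorm(-abs(tstat)),
             row.names = NULL)
}

#' Standard errors of a fitted model
#'
#' Square roots of the diagonal of the inverse observed information
#' (numerical Hessian of the marginal log-likelihood), delta-method mapped
#' to the natural scale for `alpha` and `phi`.  Supplying `data` recomputes
#' them, optionally with a different finite-difference step.
#'
#' @param fit a `zinb_fit`.
#' @param data the fitting panel; NULL returns the stored vector.
#' @param step relative central-difference step.
#' @return named numeric vector of standard errors.
#' @export
standard_errors <- function(fit, data = NULL, step = NULL) {
  if (is.null(data)) {
    if (is.null(fit$se)) stop("fit carries no standard errors", call. = FALSE)
    return(fit$se)
  }
  add_standard_errors(fit, data, step = step)$se
}

#' Information criteria of a fit
#'
#' AIC = -2 loglik + 2k and BIC = -2 loglik + k log(N) with k the number of
#' free parameters of the configuration.
#'
#' @param fit a `zinb_fit`.
#' @return named vector `c(aic, bic, neg2ll)`.
#' @export
information_criteria <- function(fit) {
  c(aic = fit$aic, bic = fit$bic, neg2ll = fit$neg2ll)
}

#' @export
coef.zinb_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.zinb_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.zinb_fit <- function(object, ...) object$vcov

#' @export
print.zinb_fit <- function(x, digits = 4, ...) {
  cat("Panel count model:", toupper(x$model),
      if (x$random != "none") paste0("(site effect: ", x$random, ")"), "\n")
  cat("N =", x$n_obs, "observations,", x$n_sites, "sites;",
      "k =", x$k, "free parameters\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, digits),
                  se = signif(se, digits), tstat = signif(tstat, 3),
                  pvalue = signif(pvalue, 3)), row.names = FALSE)
  cat(sprintf("-2LL = %.2f  AIC = %.2f  BIC = %.2f\n",
              x$neg2ll, x$aic, x$bic))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (length(x$boundary) > 0L) {
    cat("boundary fit:", paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}
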