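#' Per-observation log densities of a fitted model
#'
#' For pooled fits this is the fitted probability mass of each observed
#' count.  For random-effects fits the site effect is integrated out at the
#' observation level with the fitted `phi` (each observation treated as its
#' own integration unit), giving the marginal single-observation density
#' used by the Vuong comparison.
#'
#' @param fit a `zinb_fit`.
#' @param data the panel the model was fitted on.
#' @return numeric vector of log densities, one per row of `data`.
#' @export
obs_log_density <- function(fit, data) {
  spec <- fit$spec
  y <- data$count
  X <- panel_design(data, "count")
  Z <- if (spec$has_z) panel_design(data, "zero")
  p <- fit$params
  # singleton "sites": the by-site vector is the per-observation marginal
  ll_eval(y, X, Z, seq_along(y), length(y), p$beta_nb, p$beta_z, p$alpha,
          p$phi_sigma, p$phi_psi, fit$quad_order, spec)$by_site
}

#' Vuong non-nested test for zero inflation
#'
#' Computes the per-observation log-density ratios
#' `m_it = log f1(y_it|X_it) - log f2(y_it|X_it)` between a zero-inflated
#' fit (`fit_zi`) and its parent count fit (`fit_parent`) on the same
#' panel, and the statistic `V = mean(m) * sqrt(N) / sd(m)`, asymptotically
#' standard normal.  `V > threshold` favors the zero-inflated model,
#' `V < -threshold` the parent; otherwise the test is inconclusive.
#'
#' @param data the common fitting panel.
#' @param fit_zi zero-inflated fit (f1).
#' @param fit_parent parent count fit (f2).
#' @param threshold critical value (default 1.96, the 95% level).
#' @return object of class `vuong_result` with fields `m`, `m_bar`, `s_m`,
#'   `V`, `decision`, `threshold`.
#' @export
vuong_test <- function(data, fit_zi, fit_parent, threshold = 1.96) {
  if (fit_zi$n_obs != nrow(data) || fit_parent$n_obs != nrow(data)) {
    stop("both fits must come from the panel supplied as `data`",
         call. = FALSE)
  }
  l1 <- obs_log_density(fit_zi, data)
  l2 <- obs_log_density(fit_parent, data)
  zero_dens <- !is.finite(l1) | !is.finite(l2)
  if (any(zero_dens)) {
    stop("density is zero at observed count for row(s): ",
         paste(utils::head(which(zero_dens), 5L), collapse = ", "),
         call. = FALSE)
  }
  m <- l1 - l2
  s_m <- stats::sd(m)
  if (s_m == 0) {
    stop("degenerate comparison: the two models assign identical ",
         "densities to every observation", call. = FALSE)
  }
  m_bar <- mean(m)
  V <- m_bar * sqrt(length(m)) / s_m
  decision <- if (V > threshold) "favor_zero_inflated"
              else if (V < -threshold) "favor_parent"
              else "inconclusive"
  structure(list(m = m, m_bar = m_bar, s_m = s_m, V = V,
                 decision = decision, threshold = threshold,
                 models = c(zi = fit_zi$model, parent = fit_parent$model)),
            class = "vuong_result")
}

#' @export
print.vuong_result <- function(x, ...) {
  cat(sprintf("Vuong test (%s vs %s): V = %.3f  [threshold %.2f]\n",
              x$models["zi"], x$models["parent"], x$V, x$threshold))
  cat("decision:", x$decision, "\n")
  invisible(x)
}

#' Overdispersion decision: negative binomial versus Poisson
#'
#' Reports the fitted overdispersion `alpha`, its t-statistic, and whether
#' the NB family is preferred over Poisson at the stated level.  A boundary
#' fit (`alpha` at zero) yields a Poisson preference with a boundary note.
#'
#' @param fit a fit with free `alpha` (nb, zinb or zinb_re).
#' @param level confidence level for the two-sided decision.
#' @return list of class `overdispersion_decision`.
#' @export
overdispersion_decision <- function(fit, level = 0.95) {
  if (fit$spec$pois) {
    stop("fit has no free overdispersion parameter", call. = FALSE)
  }
  alpha <- fit$params$alpha
  se_a <- if (!is.null(fit$se)) unname(fit$se["alpha"]) else NA_real_
  tstat <- alpha / se_a
  crit <- stats::qnorm(1 - (1 - level) / 2)
  boundary <- "alpha" %in% fit$boundary
  preferred <- if (boundary) "poisson"
               else if (is.finite(tstat) && tstat > crit) "nb" else "poisson"
  structure(list(alpha = alpha, se = se_a, tstat = tstat, level = level,
                 critical = crit, preferred = preferred,
                 boundary = boundary),
            class = "overdispersion_decision")
}

#' @export
print.overdispersion_decision <- function(x, ...) {
  cat(sprintf("alpha = %.4f (t = %.2f); %s preferred at %.0f%% level%s\n",
              x$alpha, x$tstat, toupper(x$preferred), 100 * x$level,
              if (x$boundary) " [boundary fit]" else ""))
  invisible(x)
}
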