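#' Linear predictors of the two mixture states
#'
#' Computes, row by row, the count-state mean
#' `lambda_it = exp(beta_nb . X_NBit + sigma_i)`, the zero-state probability
#' `q_it = logistic(beta_z . X_zit + psi_i)`, and the derived ratio
#' `u_it = (1/alpha) / ((1/alpha) + lambda_it)`.  Site effects default to
#' zero, which gives the pooled (population-level) predictors.  Linear
#' predictors beyond +/-`clamp` are clamped in log space; the number of
#' clamped rows is recorded in the result.
#'
#' @param data a [panel_data()].
#' @param params a [zinb_params()] matching the panel's designs.
#' @param sigma_i,psi_i named numeric vectors of site effects (names are
#'   site ids) or NULL for zeros.
#' @param clamp absolute bound applied to both linear predictors.
#' @return list with `lambda`, `q`, `u` (row vectors) and `n_clamped`.
#' @export
linear_predictors <- function(data, params, sigma_i = NULL, psi_i = NULL,
                              clamp = 30) {
  check_params_match(params, data)
  X <- panel_design(data, "count")
  eta <- drop(X %*% params$beta_nb)
  if (!is.null(sigma_i)) eta <- eta + site_effect_rows(data, sigma_i)
  zeta <- rep(-Inf, nrow(data))  # q = 0 when no zero state
  if (!is.null(params$beta_z)) {
    Z <- panel_design(data, "zero")
    zeta <- drop(Z %*% params$beta_z)
    if (!is.null(psi_i)) zeta <- zeta + site_effect_rows(data, psi_i)
  }
  n_clamped <- sum(abs(eta) > clamp) + sum(abs(zeta) > clamp & is.finite(zeta))
  eta <- pmin(pmax(eta, -clamp), clamp)
  zeta[is.finite(zeta)] <- pmin(pmax(zeta[is.finite(zeta)], -clamp), clamp)
  lambda <- unname(exp(eta))
  r <- 1 / params$alpha
  list(lambda = lambda, q = unname(stats::plogis(zeta)),
       u = r / (r + lambda), n_clamped = n_clamped)
}

site_effect_rows <- function(data, eff) {
  ids <- unique(data$site_id)
  if (is.null(names(eff))) {
    if (length(eff) != length(ids)) {
      stop("site effects must be named or match the number of sites",
           call. = FALSE)
    }
    names(eff) <- ids
  }
  missing_ids <- setdiff(ids, names(eff))
  if (length(missing_ids) > 0L) {
    stop("no site effect supplied for site(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  unname(eff[data$site_id])
}
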