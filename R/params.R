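#' Parameter set of the random-effects zero-inflated negative binomial model
#'
#' Bundles the count-state coefficients `beta_nb` (intercept first), the
#' zero-state coefficients `beta_z`, the overdispersion `alpha` (> 0;
#' Poisson limit as `alpha -> 0`), and the standard deviations `phi_sigma`
#' and `phi_psi` (>= 0) of the independent normal site effects in the count
#' and zero states.  Degenerate sub-models are expressed by fixing
#' components: `phi = 0` removes a random effect, an empty zero state
#' (`beta_z = NULL` with `q = 0`) gives the plain count model.
#'
#' @param beta_nb numeric vector, count-state coefficients incl. intercept.
#' @param beta_z numeric vector or NULL, zero-state coefficients incl.
#'   intercept; NULL means no zero state (q identically 0).
#' @param alpha overdispersion, > 0 (use a tiny value for the Poisson limit).
#' @param phi_sigma,phi_psi site-effect standard deviations, >= 0.
#' @return object of class `zinb_params`.
#' @export
zinb_params <- function(beta_nb, beta_z = NULL, alpha = 1,
                        phi_sigma = 0, phi_psi = 0) {
  stopifnot(is.numeric(beta_nb), length(beta_nb) >= 1L,
            all(is.finite(beta_nb)))
  if (!is.null(beta_z)) {
    stopifnot(is.numeric(beta_z), length(beta_z) >= 1L, all(is.finite(beta_z)))
  }
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (phi_sigma < 0 || phi_psi < 0) stop("phi must be >= 0", call. = FALSE)
  structure(list(beta_nb = beta_nb, beta_z = beta_z, alpha = alpha,
                 phi_sigma = phi_sigma, phi_psi = phi_psi),
            class = "zinb_params")
}

#' @export
print.zinb_params <- function(x, ...) {
  cat("ZINB-RE parameters\n")
  cat("  beta_nb:", format(x$beta_nb, digits = 4), "\n")
  if (!is.null(x$beta_z)) cat("  beta_z :", format(x$beta_z, digits = 4), "\n")
  cat("  alpha  :", format(x$alpha, digits = 4),
      " phi_sigma:", format(x$phi_sigma, digits = 4),
      " phi_psi:", format(x$phi_psi, digits = 4), "\n")
  invisible(x)
}

check_params_match <- function(params, data) {
  pc <- length(attr(data, "count_design")) + 1L
  if (length(params$beta_nb) != pc) {
    stop("beta_nb has length ", length(params$beta_nb),
         " but the count design implies ", pc, call. = FALSE)
  }
  if (!is.null(params$beta_z)) {
    pz <- length(attr(data, "zero_design")) + 1L
    if (length(params$beta_z) != pz) {
      stop("beta_z has length ", length(params$beta_z),
           " but the zero design implies ", pz, call. = FALSE)
    }
  }
  invisible(TRUE)
}
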