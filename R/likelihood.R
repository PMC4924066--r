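# Marginal likelihood engine for the model ladder
# poisson -> nb -> zip -> zinb -> zinb with normal site effects.
#
# All density arithmetic is in log space.  Site random effects are
# integrated out by non-adaptive Gauss-Hermite quadrature: for
# sigma_i ~ N(0, phi^2),
#   integral g(sigma) dN(sigma) = (1/sqrt(pi)) * sum_k w_k g(sqrt(2) phi x_k)
# with (x_k, w_k) the Hermite nodes and weights.  When both states carry a
# random effect the product rule over node pairs is used.  phi = 0 collapses
# the corresponding integral to a point mass at zero exactly.
#
# Crash counts take very few distinct values, so the gamma-function terms
# lgamma(r + y) and digamma(r + y) are evaluated once per distinct count
# and indexed, which dominates the speedup over naive vectorization.

# memoized Gauss-Hermite nodes
gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(order) {
  check_quad_order(order)
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    gh_cache[[key]] <- if (order == 1) {
      list(x = 0, w = sqrt(pi))  # single Hermite node at the origin
    } else {
      pracma::gaussHermite(as.integer(order))
    }
  }
  gh_cache[[key]]
}

check_quad_order <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("quad_order must be a positive integer", call. = FALSE)
  }
  invisible(order)
}

# per-panel precomputations that depend only on the counts
ll_pre <- function(y) {
  uy <- sort(unique(y))
  list(uy = uy, yidx = match(y, uy), lgy1 = lgamma(y + 1), iz = which(y == 0L))
}

# Per-row log density and derivatives at given linear predictors.
# eta: count-state predictor (lambda = exp(eta)); zc: zero-state cache
# (list logq, log1mq, q) or NULL for no zero state; rc: count-state cache
# (list pois, r, and per-distinct-count gamma tables).  For y = 0 rows the
# count-branch derivatives are the all-rows formulas damped by the
# posterior weight of the count branch, which the mixture algebra reduces
# to exactly.
row_terms <- function(y, eta, zc, rc, pre, want_grad = FALSE) {
  lambda <- exp(eta)
  iz <- pre$iz
  if (rc$pois) {
    lcount <- y * eta - lambda - pre$lgy1
  } else {
    r <- rc$r
    den <- r + lambda
    lden <- log(den)
    # r*(log r - log(r + lambda)) written as -r*log1p(lambda/r): stable in
    # the Poisson limit r -> Inf where the direct difference cancels
    lr_term <- -r * log1p(lambda / r)
    lcount <- rc$lg_tab[pre$yidx] - pre$lgy1 + lr_term + y * (eta - lden)
  }
  if (!is.null(zc)) {
    logf <- zc$log1mq + lcount
    logf[iz] <- log_add(zc$logq[iz], logf[iz])
  } else {
    logf <- lcount
  }
  out <- list(logf = logf)
  if (want_grad) {
    g_eta <- if (rc$pois) y - lambda else r * (y - lambda) / den
    if (!rc$pois) {
      g_a <- -r * (rc$dg_tab[pre$yidx] - log1p(lambda / r) + 1 -
                     (r + y) / den)
    }
    if (!is.null(zc)) {
      w0 <- exp(zc$log1mq[iz] + lcount[iz] - logf[iz])  # count-branch weight
      g_eta[iz] <- w0 * g_eta[iz]
      g_zeta <- -zc$q
      g_zeta[iz] <- exp(zc$logq[iz] + zc$log1mq[iz] - logf[iz]) *
        (1 - exp(lcount[iz]))
      if (!rc$pois) g_a[iz] <- w0 * g_a[iz]
      out$g_zeta <- g_zeta
    }
    out$g_eta <- g_eta
    if (!rc$pois) out$g_a <- g_a
  }
  out
}

zero_cache <- function(zeta) {
  list(logq = stats::plogis(zeta, log.p = TRUE),
       log1mq = stats::plogis(-zeta, log.p = TRUE),
       q = stats::plogis(zeta))
}

count_cache <- function(alpha, pois, pre) {
  if (pois) return(list(pois = TRUE))
  r <- 1 / max(alpha, 1e-12)
  list(pois = FALSE, r = r,
       lg_tab = lgamma(r + pre$uy) - lgamma(r),
       dg_tab = digamma(r + pre$uy) - digamma(r))
}

# Core evaluator.  spec: list(pois, has_z, re_sigma, re_psi).
# Returns total loglik, per-site logliks and (optionally) the gradient
# w.r.t. (beta_nb, beta_z, log alpha, log phi_sigma, log phi_psi) in the
# components present in the model.
ll_eval <- function(y, X, Z, site, n_site, beta_nb, beta_z, alpha,
                    phi_sigma, phi_psi, quad_order, spec,
                    want_grad = FALSE, clamp = 30, pre = NULL) {
  check_quad_order(quad_order)
  if (is.null(pre)) pre <- ll_pre(y)
  eta0 <- pmin(pmax(drop(X %*% beta_nb), -clamp), clamp)
  zeta0 <- if (spec$has_z) pmin(pmax(drop(Z %*% beta_z), -clamp), clamp)
  rc <- count_cache(alpha, spec$pois, pre)
  use_s <- spec$re_sigma && phi_sigma > 0
  use_p <- spec$re_psi && phi_psi > 0

  gh_s <- if (use_s) gh_nodes(quad_order)
  gh_p <- if (use_p) gh_nodes(quad_order)
  s_nodes <- if (use_s) sqrt(2) * phi_sigma * gh_s$x else 0
  p_nodes <- if (use_p) sqrt(2) * phi_psi * gh_p$x else 0
  lw_s <- if (use_s) log(gh_s$w) - 0.5 * log(pi) else 0
  lw_p <- if (use_p) log(gh_p$w) - 0.5 * log(pi) else 0
  grid <- expand.grid(ks = seq_along(s_nodes), kp = seq_along(p_nodes))
  K <- nrow(grid)
  s_k <- s_nodes[grid$ks]
  p_k <- p_nodes[grid$kp]
  lw_k <- lw_s[grid$ks] + lw_p[grid$kp]

  # the zero-state cache is shared across nodes unless psi is integrated
  zc0 <- if (spec$has_z && !use_p) zero_cache(zeta0)

  if (K == 1L) {  # pooled model, phi = 0 collapse, or single-node quadrature
    zc <- if (spec$has_z) zc0 %||% zero_cache(zeta0 + p_k[1L])
    rt <- row_terms(y, eta0 + s_k[1L], zc, rc, pre, want_grad)
    by_site <- rowsum_vec(rt$logf, site, n_site) + lw_k[1L]
    if (any(is.nan(by_site))) {
      stop("non-finite likelihood contribution for site index ",
           which(is.nan(by_site))[1L], call. = FALSE)
    }
    out <- list(loglik = sum(by_site), by_site = by_site)
    if (want_grad) {
      grad <- list(beta_nb = drop(crossprod(X, rt$g_eta)))
      if (spec$has_z) grad$beta_z <- drop(crossprod(Z, rt$g_zeta))
      if (!spec$pois) grad$log_alpha <- sum(rt$g_a)
      if (spec$re_sigma) grad$log_phi_sigma <- 0
      if (spec$re_psi) grad$log_phi_psi <- 0
      out$grad <- grad
    }
    return(out)
  }

  n <- length(y)
  Lf <- matrix(0, n_site, K)
  if (want_grad) {
    GE <- matrix(0, n, K)
    GZ <- if (spec$has_z) matrix(0, n, K)
    GA <- if (!spec$pois) matrix(0, n, K)
  }
  for (k in seq_len(K)) {
    zc <- if (spec$has_z) zc0 %||% zero_cache(zeta0 + p_k[k])
    rt <- row_terms(y, eta0 + s_k[k], zc, rc, pre, want_grad)
    Lf[, k] <- rowsum_vec(rt$logf, site, n_site)
    if (want_grad) {
      GE[, k] <- rt$g_eta
      if (spec$has_z) GZ[, k] <- rt$g_zeta
      if (!spec$pois) GA[, k] <- rt$g_a
    }
  }
  if (any(is.nan(Lf))) {
    bad <- which(is.nan(Lf), arr.ind = TRUE)[1L, ]
    stop("non-finite integrand at quadrature node ", bad[2L],
         " for site index ", bad[1L], call. = FALSE)
  }
  Lw <- sweep(Lf, 2L, lw_k, "+")
  m <- apply(Lw, 1L, max)
  P <- exp(Lw - m)
  S <- rowSums(P)
  by_site <- m + log(S)
  out <- list(loglik = sum(by_site), by_site = by_site)
  if (want_grad) {
    Pi <- P / S                 # posterior node weights per site
    Wr <- Pi[site, , drop = FALSE]  # mapped to rows
    WE <- Wr * GE
    ge <- rowSums(WE)
    grad <- list(beta_nb = drop(crossprod(X, ge)))
    if (spec$has_z) {
      WZ <- Wr * GZ
      grad$beta_z <- drop(crossprod(Z, rowSums(WZ)))
    }
    if (!spec$pois) grad$log_alpha <- sum(Wr * GA)
    if (spec$re_sigma) {
      grad$log_phi_sigma <- if (use_s) sum(WE %*% s_k) else 0
    }
    if (spec$re_psi) {
      grad$log_phi_psi <- if (use_p) sum(WZ %*% p_k) else 0
    }
    out$grad <- grad
  }
  out
}

rowsum_vec <- function(x, site, n_site) {
  out <- numeric(n_site)
  # rowsum() keeps -Inf groups at -Inf correctly; site is a 1-based index
  rs <- rowsum(x, site)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

model_frame <- function(data, params) {
  check_params_match(params, data)
  sites <- unique(data$site_id)
  list(y = data$count,
       X = panel_design(data, "count"),
       Z = if (!is.null(params$beta_z)) panel_design(data, "zero"),
       site = match(data$site_id, sites),
       sites = sites)
}

#' Marginal log-likelihood of one site panel
#'
#' Evaluates log of the double integral over the site effects of the
#' product over the site's observations of the zero-inflated negative
#' binomial mass, the effects integrated against their independent normal
#' laws by (product) Gauss-Hermite quadrature.  `phi = 0` collapses the
#' corresponding integral to a point mass exactly, and `quad_order = 1`
#' places the single Hermite node at the origin, so both reduce to the
#' pooled log-likelihood.
#'
#' @param site_rows a [panel_data()] slice whose rows share one `site_id`.
#' @param params a [zinb_params()].
#' @param quad_order Gauss-Hermite order per random dimension (>= 1).
#' @return the site marginal log-likelihood (scalar).
#' @export
site_marginal_loglik <- function(site_rows, params, quad_order = 15) {
  if (length(unique(site_rows$site_id)) != 1L) {
    stop("site_rows must contain exactly one site", call. = FALSE)
  }
  total_loglik(site_rows, params, quad_order)
}

#' Marginal log-likelihood of the whole panel
#'
#' Sum of [site_marginal_loglik()] over sites; invariant to site ordering.
#'
#' @inheritParams site_marginal_loglik
#' @param data a [panel_data()].
#' @return total marginal log-likelihood (scalar).
#' @export
total_loglik <- function(data, params, quad_order = 15) {
  mf <- model_frame(data, params)
  spec <- list(pois = FALSE, has_z = !is.null(params$beta_z),
               re_sigma = params$phi_sigma > 0, re_psi = params$phi_psi > 0)
  ll_eval(mf$y, mf$X, mf$Z, mf$site, length(mf$sites),
          params$beta_nb, params$beta_z, params$alpha,
          params$phi_sigma, params$phi_psi, quad_order, spec)$loglik
}
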