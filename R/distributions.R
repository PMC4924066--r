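#' Negative binomial probability mass in the overdispersion parameterization
#'
#' P(y) = Gamma((1/a)+y) / (Gamma(1/a) Gamma(y+1)) * u^(1/a) * (1-u)^y with
#' u = (1/a) / ((1/a) + lambda), so that E(y) = lambda and
#' Var(y) = lambda (1 + a lambda).  As `alpha -> 0` the mass converges to
#' the Poisson pmf.  All arithmetic is in log space (log-gamma), so small
#' `alpha` and large `y` do not overflow.
#'
#' @param y non-negative integer count(s).
#' @param lambda positive mean(s).
#' @param alpha positive overdispersion.
#' @param log return log-probability.
#' @return probability (or log-probability), vectorized over arguments.
#' @examples
#' nb_pmf(0, lambda = 1, alpha = 1e-8)   # ~ exp(-1), the Poisson limit
#' nb_pmf(0, 0.5, 2) - (1 + 2 * 0.5)^(-1 / 2)  # y = 0 closed form
#' @export
nb_pmf <- function(y, lambda, alpha, log = FALSE) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("y must be a non-negative integer", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("lambda must be > 0", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be > 0", call. = FALSE)
  }
  lp <- nb_logpmf(y, lambda, 1 / alpha)
  if (log) lp else exp(lp)
}

# log NB mass, r = 1/alpha; vectorized, no input checks.  The u^r factor is
# written -r*log1p(lambda/r), stable in the Poisson limit r -> Inf.
nb_logpmf <- function(y, lambda, r) {
  lgamma(r + y) - lgamma(r) - lgamma(y + 1) -
    r * log1p(lambda / r) + y * (log(lambda) - log(r + lambda))
}

#' Zero-inflated negative binomial probability mass
#'
#' A two-state mixture: with probability `q` the observation sits in a
#' structurally safe zero state, otherwise the count is negative binomial.
#' P(0) = q + (1-q) NB(0); P(y>0) = (1-q) NB(y).
#'
#' @inheritParams nb_pmf
#' @param q zero-state probability in \[0, 1\].
#' @return probability (or log-probability), vectorized.
#' @export
zinb_pmf <- function(y, lambda, q, alpha, log = FALSE) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  lnb <- nb_pmf(y, lambda, alpha, log = TRUE)
  n <- max(length(y), length(lambda), length(q), length(alpha))
  y <- rep_len(y, n); q <- rep_len(q, n); lnb <- rep_len(lnb, n)
  lp <- ifelse(y == 0,
               log_add(log(q), log1p(-q) + lnb),
               log1p(-q) + lnb)
  # q = 1 puts all mass on zero regardless of the NB branch
  lp[q == 1] <- ifelse(y[q == 1] == 0, 0, -Inf)
  if (log) lp else exp(lp)
}

# log(exp(a) + exp(b)), elementwise-stable
log_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[m == -Inf] <- -Inf
  out
}

# log-sum-exp over a vector (or matrix rows when given a matrix and dim)
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Expected count of the zero-inflated mixture
#'
#' E(n) = (1 - q) * lambda: the count-state mean deflated by the zero-state
#' probability.
#'
#' @param lambda positive count-state mean(s).
#' @param q zero-state probability in \[0, 1\].
#' @return non-negative expected count, vectorized.
#' @export
expected_count <- function(lambda, q) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("lambda must be > 0", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  (1 - q) * lambda
}

#' Draw zero-inflated negative binomial counts
#'
#' Forward simulation used by the synthetic-data generator and as a sampling
#' oracle: a structural zero with probability `q`, otherwise a gamma-mixed
#' Poisson draw (rate `lambda * G`, `G ~ Gamma(1/alpha, scale alpha)`),
#' which is the generative representation of the NB distribution.  The
#' latent state is returned alongside the counts.
#'
#' @param n number of draws.
#' @param lambda,q,alpha mixture parameters, recycled to length `n`;
#'   `alpha = 0` gives Poisson counts.
#' @return list with integer `count` and logical `structural_zero`.
#' @export
rzinb <- function(n, lambda, q = 0, alpha = 0) {
  lambda <- rep_len(lambda, n)
  q <- rep_len(q, n)
  structural <- stats::runif(n) < q
  rate <- lambda
  if (alpha > 0) {
    rate <- lambda * stats::rgamma(n, shape = 1 / alpha, scale = alpha)
  }
  count <- stats::rpois(n, rate)
  count[structural] <- 0L
  list(count = as.integer(count), structural_zero = structural)
}
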