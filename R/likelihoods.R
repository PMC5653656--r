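#' Negative-binomial log-likelihood in success-odds parameterization
#'
#' Log-likelihood of replicate counts under the Poisson-Gamma mixture
#' \eqn{x_i \sim Po(\mu_i)}, \eqn{\mu_i \sim Ga(r, p/(1-p))}, whose marginal
#' is negative binomial with size \eqn{r} and mean \eqn{r\,p/(1-p)}.
#' The log-pmf is evaluated through `lgamma` so that real-valued
#' (depth-normalized) counts are accepted; at integer counts it agrees with
#' [stats::dnbinom()] exactly.
#'
#' @param counts numeric vector of non-negative counts (replicates).
#' @param r dispersion (size) parameter, `r > 0`; the reciprocal of the
#'   usual overdispersion \eqn{d} in \eqn{Var = m + d\,m^2}.
#' @param p success probability in `(0,1)`; the NB mean is `r * p / (1 - p)`.
#' @return Sum of log-pmf values over `counts` (a single number).
#' @examples
#' nb_loglik(0, r = 1, p = 0.5)        # log(0.5): geometric P(0)
#' nb_loglik(c(3, 5, 4), r = 10, p = 0.3)
#' @export
nb_loglik <- function(counts, r, p) {
  stopifnot(is.finite(r), r > 0, is.finite(p), p > 0, p < 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  # log pmf: C(x+r-1, x) p^x (1-p)^r with the continuous lgamma extension
  sum(lgamma(counts + r) - lgamma(r) - lgamma(counts + 1) +
        counts * log(p) + r * log1p(-p))
}

## NB log-likelihood parameterized by mean m (= r p/(1-p)); p = m/(r+m)
nb_loglik_mean <- function(counts, r, m) {
  m <- max(m, 1e-12)
  nb_loglik(counts, r, p = m / (r + m))
}

#' Beta-binomial log-likelihood in mean/concentration parameterization
#'
#' Log-likelihood of F1 allele counts under
#' \eqn{z_j \sim Bi(n_j, p_j)}, \eqn{p_j \sim Be(\alpha, \beta)} with
#' \eqn{\alpha = mean \cdot concentration} and
#' \eqn{\beta = (1 - mean) \cdot concentration}.
#'
#' @param k numeric vector of allele-A counts, `0 <= k <= n`.
#' @param n numeric vector of total counts per replicate (recycled if scalar).
#' @param mean beta mean \eqn{\alpha/(\alpha+\beta)} in `(0,1)`.
#' @param concentration beta concentration \eqn{\alpha+\beta > 0}.
#' @return Sum of log-pmf values (a single number).
#' @examples
#' betabin_loglik(3, 10, mean = 0.5, concentration = 2)  # log(1/11): uniform
#' @export
betabin_loglik <- function(k, n, mean, concentration) {
  stopifnot(mean > 0, mean < 1, concentration > 0)
  if (length(n) == 1L) n <- rep(n, length(k))
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  a <- mean * concentration
  b <- (1 - mean) * concentration
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

## Method-of-moments start for the beta-binomial concentration, given a mean.
## Returns a value clamped to a safe optimization range.
bb_moment_concentration <- function(k, n, mean) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(k) < 2L) return(10)
  f <- k / n
  s2 <- stats::var(f)
  inv_n <- base::mean(1 / n)
  denom <- mean * (1 - mean)
  if (!is.finite(s2) || s2 <= 0 || denom <= 0) return(1e4)
  rho <- (s2 - denom * inv_n) / (denom * (1 - inv_n))
  rho <- min(max(rho, 1e-6), 1 - 1e-6)
  conc <- (1 - rho) / rho
  min(max(conc, 0.1), 1e6)
}

## 1-D maximization of the beta-binomial likelihood over log concentration
## at a fixed mean. Returns list(concentration, loglik).
bb_fit_concentration <- function(k, n, mean,
                                 lower = log(1e-2), upper = log(1e8)) {
  f <- function(lc) -betabin_loglik(k, n, mean, exp(lc))
  opt <- stats::optimize(f, interval = c(lower, upper), tol = 1e-10)
  list(concentration = exp(opt$minimum), loglik = -opt$objective)
}

#' Bayesian information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return `k * log(n) - 2 * loglik`.
#' @export
bic <- function(loglik, k, n) k * log(n) - 2 * loglik
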