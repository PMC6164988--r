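#' The quantile-parameterized log-Laplace distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the log-Laplace (LL) distribution in its quantile parameterization
#' \code{LL(mu_tau, tau, sigma)}: if \eqn{M \sim LL(\mu_\tau, \tau, \sigma)}
#' then \eqn{\log M} has an asymmetric Laplace (AL) distribution with
#' location \eqn{\mu_\tau}, so that \eqn{P(M \le e^{\mu_\tau}) = \tau}
#' exactly.  This makes \eqn{e^{\mu_\tau}} the \eqn{\tau}-quantile of the
#' distribution by construction, which is what lets a regression on
#' \eqn{\mu_\tau} model a chosen quantile of relative risk directly.
#'
#' The density is
#' \deqn{f(\mu) = \frac{1}{\mu}\,\frac{\tau(1-\tau)}{\sigma}
#'   \exp\{-\rho_\tau(\log \mu - \mu_\tau)/\sigma\}, \quad \mu > 0,}
#' where \eqn{\rho_\tau(r) = r(\tau - 1\{r < 0\})} is the check (quantile
#' regression) loss.  Equivalently, with \eqn{\delta = e^{\mu_\tau}},
#' \eqn{a = \tau/\sigma}, \eqn{b = (1-\tau)/\sigma}, this is the classical
#' three-parameter log-Laplace law \code{LL(delta, a, b)}: a power-function
#' branch below \eqn{\delta} and a Pareto tail above it (see
#' \code{\link{dloglap3}}).  Maximizing the log-density in \eqn{\mu_\tau} is
#' equivalent to minimizing summed check loss of
#' \eqn{\log \mu - \mu_\tau}, the defining objective of \eqn{\tau}-quantile
#' estimation.
#'
#' All density work is done on the log scale internally; the linear-scale
#' density is a thin wrapper, so extreme \code{x} do not underflow.
#' Parameter violations raise errors rather than clamping: silently forcing
#' \code{tau} into (0,1) or \code{sigma} positive would corrupt the quantile
#' semantics downstream.
#'
#' @param x vector of relative-risk values (> 0).
#' @param p vector of probabilities in (0,1).
#' @param n number of draws.
#' @param mu_tau location on the log scale: the log of the \eqn{\tau}-quantile.
#' @param tau quantile level, in (0,1).
#' @param sigma scale on the log scale, > 0.
#' @param log,log.p logical; return log-density / accept log-probabilities.
#' @return \code{dloglap} the density, \code{ploglap} the distribution
#'   function, \code{qloglap} the quantile function, \code{rloglap} a vector
#'   of draws.
#' @examples
#' dloglap(1, mu_tau = 0, tau = 0.5, sigma = 1)   # 0.25 at the location
#' ploglap(exp(0.3), mu_tau = 0.3, tau = 0.9, sigma = 2)  # = tau
#' qloglap(0.5, mu_tau = 0, tau = 0.5, sigma = 1) # symmetric median = 1
#' @name loglaplace
NULL

check_ll_params <- function(mu_tau, tau, sigma) {
  if (!all(is.finite(mu_tau))) stop("'mu_tau' must be finite", call. = FALSE)
  if (!all(is.finite(tau)) || any(tau <= 0) || any(tau >= 1))
    stop("'tau' must lie strictly in (0, 1)", call. = FALSE)
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

#' Check (quantile) loss
#'
#' \eqn{\rho_\tau(r) = r(\tau - 1\{r < 0\})}: positive residuals are
#' weighted by \eqn{\tau}, negative ones by \eqn{1-\tau}.  The
#' \eqn{\tau}-quantile is the minimizer of expected check loss, and the
#' log-Laplace log-likelihood in \code{mu_tau} is, up to constants,
#' \eqn{-\sum \rho_\tau(\log\mu - \mu_\tau)/\sigma}, so likelihood
#' maximization and check-loss minimization coincide.
#'
#' @param r residual vector.
#' @param tau quantile level in (0,1).
#' @return nonnegative loss, vectorized over \code{r}.
#' @export
check_loss <- function(r, tau) {
  if (any(tau <= 0) || any(tau >= 1))
    stop("'tau' must lie strictly in (0, 1)", call. = FALSE)
  r * (tau - (r < 0))
}

#' @rdname loglaplace
#' @export
dloglap <- function(x, mu_tau = 0, tau = 0.5, sigma = 1, log = FALSE) {
  check_ll_params(mu_tau, tau, sigma)
  if (any(x <= 0 & is.finite(x))) stop("'x' must be strictly positive", call. = FALSE)
  lx <- base::log(x)
  ld <- base::log(tau) + log1p(-tau) - base::log(sigma) - lx -
    check_loss(lx - mu_tau, tau) / sigma
  if (log) ld else exp(ld)
}

#' @rdname loglaplace
#' @export
ploglap <- function(x, mu_tau = 0, tau = 0.5, sigma = 1, log.p = FALSE) {
  check_ll_params(mu_tau, tau, sigma)
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  r <- (base::log(x) - mu_tau) / sigma
  pr <- ifelse(r < 0,
               tau * exp((1 - tau) * r),
               1 - (1 - tau) * exp(-tau * r))
  pr[x == 0] <- 0
  if (log.p) base::log(pr) else pr
}

#' @rdname loglaplace
#' @export
qloglap <- function(p, mu_tau = 0, tau = 0.5, sigma = 1) {
  check_ll_params(mu_tau, tau, sigma)
  if (any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  lq <- ifelse(p <= tau,
               mu_tau + sigma * base::log(p / tau) / (1 - tau),
               mu_tau - sigma * base::log((1 - p) / (1 - tau)) / tau)
  exp(lq)
}

#' @rdname loglaplace
#' @param seed optional integer seed for reproducible draws; \code{NULL}
#'   uses (and advances) the current RNG state.
#' @export
rloglap <- function(n, mu_tau = 0, tau = 0.5, sigma = 1, seed = NULL) {
  check_ll_params(mu_tau, tau, sigma)
  if (length(n) != 1 || n < 1) stop("'n' must be a positive count", call. = FALSE)
  runner <- function() qloglap(runif(n), mu_tau = mu_tau, tau = tau, sigma = sigma)
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Three-parameter log-Laplace density
#'
#' The classical \code{LL(delta, a, b)} form: a power-function distribution
#' below the scale parameter \code{delta} and a Pareto tail above it,
#' \deqn{f(\mu) = \frac{1}{\delta}\frac{ab}{a+b} (\mu/\delta)^{b-1}} for
#' \eqn{0 < \mu < \delta} and
#' \deqn{f(\mu) = \frac{1}{\delta}\frac{ab}{a+b} (\delta/\mu)^{a+1}} for
#' \eqn{\mu \ge \delta}.  Identical to \code{\link{dloglap}} under
#' \code{delta = exp(mu_tau)}, \code{a = tau/sigma}, \code{b = (1-tau)/sigma}
#' (see \code{\link{ll_params}}).  For \code{b < 1} the density diverges as
#' \eqn{\mu \to 0^+} but remains integrable.
#'
#' @param x vector of relative-risk values (> 0).
#' @param delta scale (the \eqn{\tau}-quantile on the risk scale), > 0.
#' @param a upper-tail (Pareto) shape, > 0.
#' @param b lower-tail (power-function) shape, > 0.
#' @param log logical; return the log-density.
#' @export
dloglap3 <- function(x, delta, a, b, log = FALSE) {
  if (any(delta <= 0) || any(a <= 0) || any(b <= 0))
    stop("'delta', 'a' and 'b' must be strictly positive", call. = FALSE)
  if (any(x <= 0 & is.finite(x))) stop("'x' must be strictly positive", call. = FALSE)
  lr <- base::log(x) - base::log(delta)
  ld <- -base::log(delta) + base::log(a) + base::log(b) - base::log(a + b) +
    ifelse(lr < 0, (b - 1) * lr, -(a + 1) * lr)
  if (log) ld else exp(ld)
}

#' Convert between log-Laplace parameterizations
#'
#' \code{ll_params} maps the three-parameter form \code{(delta, a, b)} to the
#' quantile parameterization \code{(mu_tau, tau, sigma)};
#' \code{ll_three_params} is its inverse.  The bijection is
#' \code{delta = exp(mu_tau)}, \code{a = tau/sigma}, \code{b = (1-tau)/sigma},
#' hence \code{sigma = 1/(a+b)} and \code{tau = a/(a+b)}.
#'
#' @param delta,a,b three-parameter form (all > 0).
#' @param mu_tau,tau,sigma quantile parameterization.
#' @return a named list with the fields of the other parameterization.
#' @export
ll_params <- function(delta, a, b) {
  if (any(delta <= 0) || any(a <= 0) || any(b <= 0))
    stop("'delta', 'a' and 'b' must be strictly positive", call. = FALSE)
  list(mu_tau = base::log(delta), tau = a / (a + b), sigma = 1 / (a + b))
}

#' @rdname ll_params
#' @export
ll_three_params <- function(mu_tau, tau, sigma) {
  check_ll_params(mu_tau, tau, sigma)
  list(delta = exp(mu_tau), a = tau / sigma, b = (1 - tau) / sigma)
}

# Asymmetric Laplace log-density on the log scale: the law of log(M) when
# M ~ LL(mu_tau, tau, sigma).  Used as the quantile-error prior in the
# hierarchical model, where it is cheaper to work with log-risk directly.
dal <- function(x, location = 0, tau = 0.5, sigma = 1, log = FALSE) {
  check_ll_params(location, tau, sigma)
  ld <- base::log(tau) + log1p(-tau) - base::log(sigma) -
    check_loss(x - location, tau) / sigma
  if (log) ld else exp(ld)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library calls do not clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
      stop("'seed' must be a single finite number", call. = FALSE)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
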