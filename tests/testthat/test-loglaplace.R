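# Parameter grid used across the distribution tests: quantile levels and
# scales spanning light and heavy lower tails (b = (1-tau)/sigma < 1 makes
# the density diverge at the origin).
ll_grid <- expand.grid(mu_tau = c(-0.5, 0, 0.3),
                       tau = c(0.1, 0.5, 0.9),
                       sigma = c(0.1, 0.5, 1, 2))

quad_total <- function(mu_tau, tau, sigma) {
  # split at the kink; the lower piece may have an integrable singularity
  f <- function(x) dloglap(x, mu_tau, tau, sigma)
  lo <- integrate(f, 0, exp(mu_tau), rel.tol = 1e-10)$value
  hi <- integrate(f, exp(mu_tau), Inf, rel.tol = 1e-10)$value
  lo + hi
}

test_that("density matches its closed forms at and around the location", {
  expect_equal(dloglap(1, 0, 0.5, 1), 0.25)
  for (i in seq_len(nrow(ll_grid))) {
    p <- ll_grid[i, ]
    expect_equal(dloglap(exp(p$mu_tau), p$mu_tau, p$tau, p$sigma),
                 p$tau * (1 - p$tau) / (p$sigma * exp(p$mu_tau)))
  }
  # independent evaluation through the three-parameter form at mu = e,
  # mu_tau = 0, tau = 0.5, sigma = 1: delta = 1, a = b = 1/2, so
  # f(e) = (ab/(a+b)) e^{-(a+1)} = 0.25 e^{-3/2}
  expect_equal(dloglap(exp(1), 0, 0.5, 1), 0.25 * exp(-1.5))
})

test_that("quantile and three-parameter forms agree under the bijection", {
  xs <- c(0.05, 0.3, 1, 2.7, 10, 120)
  for (i in seq_len(nrow(ll_grid))) {
    p <- ll_grid[i, ]
    tp <- ll_three_params(p$mu_tau, p$tau, p$sigma)
    expect_equal(dloglap(xs, p$mu_tau, p$tau, p$sigma),
                 dloglap3(xs, tp$delta, tp$a, tp$b), tolerance = 1e-12)
    # round trip is the identity
    back <- ll_params(tp$delta, tp$a, tp$b)
    expect_equal(back$mu_tau, p$mu_tau, tolerance = 1e-12)
    expect_equal(back$tau, p$tau, tolerance = 1e-12)
    expect_equal(back$sigma, p$sigma, tolerance = 1e-12)
  }
  expect_equal(dloglap3(1, 1, 1, 1), 0.5)
  # continuity at the kink: both branches meet at ab/(delta(a+b))
  expect_equal(dloglap3(2, 2, 3, 0.5), 3 * 0.5 / (2 * 3.5))
})

test_that("density integrates to one, including diverging-origin cases", {
  for (i in seq_len(nrow(ll_grid))) {
    p <- ll_grid[i, ]
    expect_equal(quad_total(p$mu_tau, p$tau, p$sigma), 1, tolerance = 1e-6)
  }
  # b = (1-0.5)/2 = 0.25 < 1: density unbounded near zero, still mass one
  expect_gt(dloglap(1e-8, 0, 0.5, 2), dloglap(1e-4, 0, 0.5, 2))
  expect_equal(quad_total(0, 0.5, 2), 1, tolerance = 1e-6)
})

test_that("distribution function has the quantile identity and correct limits", {
  for (i in seq_len(nrow(ll_grid))) {
    p <- ll_grid[i, ]
    # closed-form identity; exact up to the one rounding in log(exp(mu_tau))
    expect_equal(ploglap(exp(p$mu_tau), p$mu_tau, p$tau, p$sigma), p$tau,
                 tolerance = 1e-14)
  }
  expect_equal(ploglap(0, 0, 0.5, 1), 0)
  expect_equal(ploglap(1e12, 0, 0.5, 1), 1, tolerance = 1e-6)
  # agreement with quadrature of the density from 0 to x
  set.seed(31)
  for (k in 1:20) {
    p <- ll_grid[sample(nrow(ll_grid), 1), ]
    x <- exp(p$mu_tau + runif(1, -2, 2))
    qv <- if (x <= exp(p$mu_tau)) {
      integrate(function(t) dloglap(t, p$mu_tau, p$tau, p$sigma),
                0, x, rel.tol = 1e-9)$value
    } else {
      p$tau + integrate(function(t) dloglap(t, p$mu_tau, p$tau, p$sigma),
                        exp(p$mu_tau), x, rel.tol = 1e-9)$value
    }
    expect_equal(ploglap(x, p$mu_tau, p$tau, p$sigma), qv, tolerance = 1e-6)
  }
})

test_that("quantile function inverts the cdf and is strictly increasing", {
  expect_equal(qloglap(0.5, 0, 0.5, 1), 1)
  for (i in seq_len(nrow(ll_grid))) {
    p <- ll_grid[i, ]
    expect_equal(qloglap(p$tau, p$mu_tau, p$tau, p$sigma), exp(p$mu_tau),
                 tolerance = 1e-12)
    probs <- c(0.01, 0.1, 0.35, 0.6, 0.9, 0.99)
    qs <- qloglap(probs, p$mu_tau, p$tau, p$sigma)
    expect_true(all(diff(qs) > 0))
    expect_equal(ploglap(qs, p$mu_tau, p$tau, p$sigma), probs,
                 tolerance = 1e-10)
  }
  # bisection oracle for a specific interior case
  target <- 0.9
  f <- function(x) ploglap(x, 0.3, 0.5, 0.4) - target
  lo <- 1e-8; hi <- 1e8
  for (k in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(qloglap(0.9, 0.3, 0.5, 0.4), sqrt(lo * hi), tolerance = 1e-6)
})

test_that("sampler is seeded, matches the cdf, and honours the quantile constraint", {
  d1 <- rloglap(1000, 0.2, 0.7, 0.8, seed = 5)
  d2 <- rloglap(1000, 0.2, 0.7, 0.8, seed = 5)
  expect_identical(d1, d2)
  big <- rloglap(1e5, 0.2, 0.7, 0.8, seed = 6)
  expect_equal(mean(big <= exp(0.2)), 0.7, tolerance = 0.01)
  ks <- suppressWarnings(
    ks.test(big, function(q) ploglap(q, 0.2, 0.7, 0.8)))
  expect_gt(ks$p.value, 0.01)
})

test_that("log of a log-Laplace variate has the asymmetric Laplace density", {
  xs <- seq(-3, 3, by = 0.25)
  for (tau in c(0.1, 0.5, 0.9)) {
    al <- arealquant:::dal(xs, location = 0.4, tau = tau, sigma = 0.6)
    # change of variables: f_X(x) = f_M(e^x) e^x
    expect_equal(al, dloglap(exp(xs), 0.4, tau, 0.6) * exp(xs),
                 tolerance = 1e-12)
  }
})

test_that("check loss weights residuals asymmetrically and drives the likelihood", {
  expect_identical(check_loss(0, 0.3), 0)
  expect_equal(check_loss(1, 0.9), 0.9)
  expect_equal(check_loss(-1, 0.9), 0.1)
  # maximizing the LL log-likelihood in mu_tau is minimizing summed check
  # loss of the log residuals: same argmin on a shared grid
  set.seed(77)
  lx <- log(rloglap(200, 0.5, 0.3, 0.7))
  grid <- seq(-1, 2, by = 0.01)
  loss <- vapply(grid, function(m) sum(check_loss(lx - m, 0.3)), numeric(1))
  loglik <- vapply(grid, function(m)
    sum(dloglap(exp(lx), m, 0.3, 0.7, log = TRUE)), numeric(1))
  expect_identical(grid[which.min(loss)], grid[which.max(loglik)])
})

test_that("domain violations raise instead of clamping", {
  expect_error(dloglap(-1, 0, 0.5, 1), "positive")
  expect_error(dloglap(1, 0, 0, 1), "tau")
  expect_error(dloglap(1, 0, 1.2, 1), "tau")
  expect_error(dloglap(1, 0, 0.5, 0), "sigma")
  expect_error(qloglap(0, 0, 0.5, 1), "p")
  expect_error(qloglap(1, 0, 0.5, 1), "p")
  expect_error(dloglap3(1, -1, 1, 1), "positive")
  expect_error(check_loss(1, 1), "tau")
})
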