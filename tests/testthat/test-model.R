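# minimal hand-built fit object for the pure summary operations
fake_fit <- function(z_draws, eta_draws, n, nt) {
  panel <- panel_data(matrix(0L, n, nt), matrix(1, n, nt))
  structure(list(model = "quantile", tau = 0.5, panel = panel,
                 chains = list(list(z = z_draws, eta = eta_draws,
                                    sd = matrix(1, nrow(z_draws), 5,
                                                dimnames = list(NULL,
                                                  c("sd_u", "sd_v", "sd_lambda",
                                                    "sd_theta", "sd_err")))))),
            class = "areal_fit")
}

test_that("linear predictor adds covariate, spatial, temporal and interaction parts", {
  expect_equal(linear_predictor(numeric(0), NULL, c(0, 0), c(0, 0),
                                c(0, 0), matrix(0, 2, 2)),
               matrix(0, 2, 2))
  eta <- linear_predictor(numeric(0), NULL, u = c(1, 0), v = c(0, 0),
                          lam = c(0, 2), theta = matrix(0, 2, 2))
  expect_equal(eta, rbind(c(1, 3), c(0, 2)))
  set.seed(2)
  u <- rnorm(3); v <- rnorm(3); lam <- rnorm(4); th <- matrix(rnorm(12), 3, 4)
  X <- array(rnorm(24), c(3, 4, 2)); beta <- c(0.5, -1)
  eta <- linear_predictor(beta, X, u, v, lam, th)
  # naive loop oracle
  ora <- matrix(NA_real_, 3, 4)
  for (i in 1:3) for (t in 1:4)
    ora[i, t] <- sum(X[i, t, ] * beta) + u[i] + v[i] + lam[t] + th[i, t]
  expect_equal(eta, ora, tolerance = 1e-12)
  expect_error(linear_predictor(numeric(0), NULL, 1:2, 1:3, 1, matrix(0, 2, 1)),
               "conform")
})

test_that("log joint isolates the intrinsic CAR term from the level", {
  g <- lattice_graph(2, 2)
  panel <- panel_data(matrix(c(2L, 0L, 5L, 1L), 2, 2),
                      matrix(2, 2, 2), region_ids = g$region_ids[1:2])
  g2 <- region_graph(rbind(g$region_ids[1:2]),
                     region_ids = g$region_ids[1:2])
  cfg <- model_config(tau = 0.7, seed = 1)
  set.seed(10)
  st <- list(z = matrix(rnorm(4), 2, 2), u = rnorm(2), v = rnorm(2),
             lam = rnorm(2), theta = matrix(rnorm(4), 2, 2),
             beta = numeric(0), sd_u = 0.8, sd_v = 0.5, sd_l = 0.4,
             sd_t = 0.6, sd_e = 1)
  base_lp <- log_joint_quantile(st, panel, g2, cfg)
  for (shift in c(-0.7, 1.3)) {
    st2 <- st; st2$u <- st$u + shift
    # the pairwise-difference ICAR term is invariant to the level, so the
    # whole change must be attributable to the error term through eta
    d_err <- sum(arealquant:::dal(st2$z, linear_predictor(numeric(0), NULL,
                    st2$u, st2$v, st2$lam, st2$theta), 0.7, 1, log = TRUE)) -
             sum(arealquant:::dal(st$z, linear_predictor(numeric(0), NULL,
                    st$u, st$v, st$lam, st$theta), 0.7, 1, log = TRUE))
    expect_equal(log_joint_quantile(st2, panel, g2, cfg) - base_lp, d_err,
                 tolerance = 1e-10)
  }
  # out-of-support states reject with -Inf, never an error
  st3 <- st; st3$sd_u <- -1
  expect_identical(log_joint_quantile(st3, panel, g2, cfg), -Inf)
  st3 <- st; st3$sd_t <- cfg$sd_prior_upper + 1
  expect_identical(log_joint_quantile(st3, panel, g2, cfg), -Inf)
})

test_that("fits are bit-reproducible under a fixed seed", {
  np <- null_panel()
  cfg <- smoke_config(seed = 33)
  f1 <- suppressWarnings(fit_quantile_model(np$panel, np$graph, cfg))
  f2 <- suppressWarnings(fit_quantile_model(np$panel, np$graph, cfg))
  expect_identical(f1$chains[[1]]$z, f2$chains[[1]]$z)
  expect_identical(f1$chains[[2]]$sd, f2$chains[[2]]$sd)
  m1 <- suppressWarnings(fit_mean_model(np$panel, np$graph, cfg))
  m2 <- suppressWarnings(fit_mean_model(np$panel, np$graph, cfg))
  expect_identical(m1$chains[[2]]$eta, m2$chains[[2]]$eta)
  # a different seed gives different draws
  f3 <- suppressWarnings(fit_quantile_model(np$panel, np$graph,
                                            smoke_config(seed = 34)))
  expect_false(identical(f1$chains[[1]]$z, f3$chains[[1]]$z))
})

test_that("single-unit posteriors concentrate near the empirical rate", {
  # one region, one period, y = 900, e = 100: relative risk near 9 with
  # Poisson SE about 0.3
  g1 <- structure(list(region_ids = "A", neighbors = list(integer(0)),
                       n_neighbors = 0L,
                       edge_mat = matrix(integer(0), 0, 2),
                       n_regions = 1L, connected = TRUE),
                  class = "region_graph")
  p1 <- panel_data(matrix(900L, 1, 1), matrix(100, 1, 1), region_ids = "A")
  cfg <- model_config(chains = 2, iterations = 4000, burn_in = 2000, seed = 8)
  fq <- suppressWarnings(fit_quantile_model(p1, g1, cfg))
  mu_q <- mean(mu_draws(fq))
  expect_gt(mu_q, 8.2); expect_lt(mu_q, 9.8)
  fm <- suppressWarnings(fit_mean_model(p1, g1, cfg))
  mu_m <- mean(mu_draws(fm))
  expect_gt(mu_m, 8.2); expect_lt(mu_m, 9.8)
})

test_that("quantile surface estimates exponentiate the eta point estimate", {
  z <- matrix(0, 10, 4); eta0 <- matrix(0, 10, 4)
  f <- fake_fit(z, eta0, 2, 2)
  expect_equal(estimate_quantile_surface(f), matrix(1, 2, 2),
               ignore_attr = TRUE)
  f2 <- fake_fit(z, matrix(log(2), 10, 4), 2, 2)
  expect_equal(estimate_quantile_surface(f2), matrix(2, 2, 2),
               ignore_attr = TRUE)
  # median summary: draws skewed so mean and median differ
  eta3 <- matrix(rep(c(0, 0, 0, 10), each = 4), 4, 4, byrow = TRUE)
  f3 <- fake_fit(matrix(0, 4, 4), eta3, 2, 2)
  expect_equal(unname(estimate_quantile_surface(f3, "median")[1, 1]), 1)
})

test_that("mean-model quantiles use type-7 interpolation of the mu draws", {
  zd <- matrix(log(c(1, 2, 3, 4)), 4, 4)
  f <- fake_fit(zd, zd, 2, 2)
  expect_equal(unname(mean_model_quantiles(f, 0.5)[1, 1]), 2.5)
  zc <- matrix(log(7), 6, 4)
  fc <- fake_fit(zc, zc, 2, 2)
  expect_equal(unname(mean_model_quantiles(fc, 0.9)[2, 2]), 7)
  # sorting-based oracle on random draws
  set.seed(99)
  zr <- matrix(log(rgamma(400, 2)), 100, 4)
  fr <- fake_fit(zr, zr, 2, 2)
  mu1 <- sort(exp(zr[, 1]))
  h <- (100 - 1) * 0.3 + 1
  ora <- mu1[floor(h)] + (h - floor(h)) * (mu1[floor(h) + 1] - mu1[floor(h)])
  expect_equal(unname(mean_model_quantiles(fr, 0.3)[1, 1]), ora,
               tolerance = 1e-12)
  expect_error(mean_model_quantiles(f, 1.1), "tau")
})

test_that("model fitting rejects invalid inputs", {
  np <- null_panel()
  gd <- region_graph(rbind(c("A", "B")), region_ids = c("A", "B", "C"))
  pd <- panel_data(matrix(0L, 3, 2), matrix(1, 3, 2),
                   region_ids = c("A", "B", "C"))
  expect_error(fit_quantile_model(pd, gd, smoke_config()), "not connected")
  expect_error(fit_quantile_model(np$panel, lattice_graph(2, 2),
                                  smoke_config()), "regions")
  expect_error(model_config(tau = 1.2), "tau")
  expect_error(model_config(chains = 1), "chains")
  expect_error(model_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(model_config(ll_scale = -1), "ll_scale")
})
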