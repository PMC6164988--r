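#' Configuration for the hierarchical spatiotemporal models
#'
#' Bundles the quantile level, the prior bound on standard deviations and
#' the MCMC settings.  Standard deviations of all Gaussian-type random
#' effects and of the error law carry a relatively non-informative
#' \code{Unif(0, sd_prior_upper)} prior (default upper bound 10).
#' The defaults — 2 chains of 8000 iterations, the first 4000 discarded —
#' are desk-scale settings; production analyses of real surveillance data
#' typically use an order of magnitude more.
#'
#' @param tau quantile level in (0,1) for the quantile model (ignored when
#'   fitting the mean comparator).
#' @param sd_prior_upper upper bound of the uniform prior on standard
#'   deviations.
#' @param chains number of chains (>= 2, so convergence can be diagnosed).
#' @param iterations total MCMC iterations per chain.
#' @param burn_in iterations discarded (and used for proposal adaptation).
#' @param thin keep every \code{thin}-th retained draw.
#' @param seed integer seed; chain \code{c} runs on a stream derived from
#'   \code{seed} and \code{c}, so a fit is bit-reproducible.
#' @param beta_prior_sd standard deviation of the diffuse zero-mean Gaussian
#'   prior on regression coefficients.
#' @param ll_scale the asymmetric-Laplace working-likelihood scale
#'   \eqn{\sigma} of the quantile error.  The default keeps it fixed at 1,
#'   the usual convention in Bayesian quantile regression: the AL is a
#'   working likelihood whose location targets the quantile, and letting
#'   its scale adapt freely is unidentified against the exchangeable
#'   space-time interaction (the scale collapses and the quantile surface
#'   degenerates to the realized noise).  Set to \code{NA} to sample it
#'   under the same \code{Unif(0, sd_prior_upper)} prior as the other
#'   scales.  Ignored by the mean model, whose Gaussian error SD is always
#'   sampled.
#' @return an object of class \code{model_config}.
#' @export
model_config <- function(tau = 0.5, sd_prior_upper = 10, chains = 2,
                         iterations = 8000, burn_in = 4000, thin = 1,
                         seed = 1, beta_prior_sd = 100, ll_scale = 1) {
  if (tau <= 0 || tau >= 1) stop("'tau' must lie in (0, 1)", call. = FALSE)
  if (!is.na(ll_scale) && ll_scale <= 0)
    stop("'ll_scale' must be positive or NA (sampled)", call. = FALSE)
  if (sd_prior_upper <= 0) stop("'sd_prior_upper' must be > 0", call. = FALSE)
  if (chains < 2) stop("use at least 2 chains (needed for R-hat)", call. = FALSE)
  if (burn_in < 0 || iterations <= burn_in)
    stop("need iterations > burn_in >= 0", call. = FALSE)
  if (thin < 1 || (iterations - burn_in) < thin)
    stop("'thin' leaves no retained draws", call. = FALSE)
  structure(list(tau = tau, sd_prior_upper = sd_prior_upper,
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), beta_prior_sd = beta_prior_sd,
                 ll_scale = ll_scale),
            class = "model_config")
}

#' Linear predictor of the spatiotemporal model
#'
#' \eqn{\eta_{it} = X_{it}^\top \beta + u_i + v_i + \lambda_t +
#' \theta_{it}}: covariate effects plus the BYM convolution spatial effect
#' (structured \code{u} + unstructured \code{v}), the temporal trend and
#' the space-time interaction.
#'
#' @param beta coefficient vector (length 0 for no covariates).
#' @param X covariate array \code{(n, T, p)} or \code{NULL}.
#' @param u,v spatial effects, length \code{n}.
#' @param lam temporal effects, length \code{T}.
#' @param theta interaction matrix \code{n x T}.
#' @return the \code{n x T} matrix \eqn{\eta}.
#' @export
linear_predictor <- function(beta, X, u, v, lam, theta) {
  theta <- as.matrix(theta)
  n <- nrow(theta); nt <- ncol(theta)
  if (length(u) != n || length(v) != n || length(lam) != nt)
    stop("effect dimensions do not conform", call. = FALSE)
  eta <- outer(u + v, rep(1, nt)) + matrix(lam, n, nt, byrow = TRUE) + theta
  if (length(beta)) {
    if (is.null(X) || length(dim(X)) != 3 || dim(X)[3] != length(beta) ||
        any(dim(X)[1:2] != c(n, nt)))
      stop("'X' must be an (n, T, length(beta)) array", call. = FALSE)
    for (k in seq_along(beta)) eta <- eta + X[, , k] * beta[k]
  }
  eta
}

#' Log joint posterior density of the quantile model (up to a constant)
#'
#' The sum of: the Poisson log-likelihood with mean \eqn{e_{it}\mu_{it}};
#' the asymmetric-Laplace log-prior of \eqn{\log\mu_{it}} centered at the
#' linear predictor (equivalently the log-Laplace prior of the relative
#' risk); the intrinsic CAR log-prior of \code{u} in pairwise-difference
#' form, with its \eqn{-(n-1)\log\sigma_u} normalizing term; zero-mean
#' Gaussian log-priors for \code{v} and \code{theta}; the RW1 log-prior for
#' \code{lambda} (first period anchored at zero); a diffuse Gaussian
#' log-prior for \code{beta}; and uniform priors on all standard deviations.
#' States outside the support (a nonpositive scale, or one at or beyond the
#' prior bound) return \code{-Inf} rather than raising, so a sampler can
#' treat them as rejections.
#'
#' @param state named list with elements \code{z} (\code{n x T} log relative
#'   risk), \code{u}, \code{v}, \code{lam}, \code{theta}, \code{beta}
#'   (may be length 0), and scalars \code{sd_u}, \code{sd_v}, \code{sd_l},
#'   \code{sd_t}, \code{sd_e}.
#' @param panel a \code{\link{panel_data}}.
#' @param graph a \code{\link{region_graph}}.
#' @param config a \code{\link{model_config}}.
#' @param model \code{"quantile"} (asymmetric-Laplace error) or
#'   \code{"mean"} (Gaussian error).
#' @return scalar log density, \code{-Inf} outside the support.
#' @export
log_joint_quantile <- function(state, panel, graph, config,
                               model = c("quantile", "mean")) {
  model <- match.arg(model)
  n <- panel$n_regions; nt <- panel$n_times
  sds <- c(state$sd_u, state$sd_v, state$sd_l, state$sd_t, state$sd_e)
  if (any(!is.finite(sds)) || any(sds <= 0) ||
      any(sds >= config$sd_prior_upper)) return(-Inf)
  if (any(!is.finite(state$z))) return(-Inf)
  eta <- linear_predictor(state$beta, panel$X, state$u, state$v,
                          state$lam, state$theta)
  mu <- exp(state$z)
  lp <- sum(dpois(panel$y, panel$e * mu, log = TRUE))
  lp <- lp + if (model == "quantile") {
    sum(dal(state$z, eta, tau = config$tau, sigma = state$sd_e, log = TRUE))
  } else {
    sum(dnorm(state$z, eta, sd = state$sd_e, log = TRUE))
  }
  em <- graph$edge_mat
  quad <- if (nrow(em)) sum((state$u[em[, 1]] - state$u[em[, 2]])^2) else 0
  lp <- lp - (n - 1) * base::log(state$sd_u) - quad / (2 * state$sd_u^2)
  lp <- lp + sum(dnorm(state$v, 0, state$sd_v, log = TRUE))
  lp <- lp + dnorm(state$lam[1], 0, state$sd_l, log = TRUE)
  if (nt > 1)
    lp <- lp + sum(dnorm(diff(state$lam), 0, state$sd_l, log = TRUE))
  lp <- lp + sum(dnorm(state$theta, 0, state$sd_t, log = TRUE))
  if (length(state$beta))
    lp <- lp + sum(dnorm(state$beta, 0, config$beta_prior_sd, log = TRUE))
  lp
}

fit_model_impl <- function(panel, graph, config, model) {
  if (!inherits(panel, "panel_data")) stop("'panel' must be a panel_data",
                                           call. = FALSE)
  if (!inherits(graph, "region_graph")) stop("'graph' must be a region_graph",
                                             call. = FALSE)
  if (!inherits(config, "model_config")) stop("'config' must be a model_config",
                                              call. = FALSE)
  stop_if_disconnected(graph)
  if (panel$n_regions != graph$n_regions ||
      !identical(panel$region_ids, graph$region_ids))
    stop("panel regions and graph regions do not match", call. = FALSE)
  n <- panel$n_regions; nt <- panel$n_times
  p <- panel$n_covariates
  pre <- list(neighbors = graph$neighbors, n_neighbors = graph$n_neighbors,
              edge_mat = graph$edge_mat, colors = graph_coloring(graph))
  t0 <- proc.time()[["elapsed"]]
  chains <- lapply(seq_len(config$chains), function(ch) {
    chain_seed <- config$seed * 1000L + 17L * ch
    start <- with_seed(chain_seed + 7L,
                       chain_start(panel$y, panel$e, panel$X, n, nt, p,
                                   config$sd_prior_upper, ch))
    run_chain(panel$y, panel$e, panel$X, pre, model, config$tau,
              config$sd_prior_upper, config$iterations, config$burn_in,
              config$thin, chain_seed, start, config$beta_prior_sd,
              config$ll_scale)
  })
  fit <- structure(list(model = model, tau = config$tau, panel = panel,
                        graph = graph, config = config, chains = chains,
                        elapsed = proc.time()[["elapsed"]] - t0),
                   class = "areal_fit")
  fit$rhat <- monitored_rhat(fit)
  bad <- fit$rhat[fit$rhat > 1.1]
  if (length(bad))
    warning("convergence not reached (R-hat > 1.1) for: ",
            paste(sprintf("%s=%.3f", names(bad), bad), collapse = ", "),
            "; consider longer chains", call. = FALSE)
  fit
}

#' Fit the Bayesian spatiotemporal quantile model
#'
#' Fits, by adaptive Metropolis-within-Gibbs MCMC, the hierarchical model
#' \deqn{y_{it} \sim Poisson(e_{it}\mu_{it}), \quad
#'       \log\mu_{it} = \eta_{\tau,it} + \epsilon_{\tau,it},}
#' where the quantile error \eqn{\epsilon_{\tau,it}} follows an asymmetric
#' Laplace law with level \eqn{\tau} (so the relative risk is log-Laplace
#' and \eqn{e^{\eta_{\tau,it}}} is its \eqn{\tau}-quantile), and
#' \eqn{\eta_{\tau,it} = X_{it}^\top\beta_\tau + u_{\tau,i} + v_{\tau,i} +
#' \lambda_{\tau,t} + \theta_{\tau,it}} carries the BYM convolution spatial
#' prior, RW1 temporal trend and exchangeable interaction described in
#' \code{\link{log_joint_quantile}}.  The ICAR effect is re-centered to
#' mean zero every sweep (its level moved into the trend, leaving the
#' fitted surface unchanged).  Chains start from overdispersed states on
#' seed-derived streams; Gelman-Rubin R-hat is computed for the monitored
#' scalars (all standard deviations, the surface-average linear predictor,
#' and any regression coefficients) and a warning is issued above 1.1.
#'
#' @param panel a \code{\link{panel_data}}.
#' @param graph a connected \code{\link{region_graph}} over the same regions.
#' @param config a \code{\link{model_config}}; its \code{tau} is the modeled
#'   quantile level.
#' @return an object of class \code{areal_fit} holding the retained draws
#'   per chain (\code{z} = log relative risk, \code{eta}, \code{u},
#'   \code{v}, \code{lam}, \code{sd}, \code{beta}), the R-hat vector and
#'   the inputs.
#' @seealso \code{\link{fit_mean_model}}, \code{\link{estimate_quantile_surface}},
#'   \code{\link{exceedence_mc}}
#' @export
fit_quantile_model <- function(panel, graph, config = model_config()) {
  fit_model_impl(panel, graph, config, "quantile")
}

#' Fit the conventional mean-regression comparator
#'
#' Same Poisson likelihood, linear predictor and random-effect priors as
#' \code{\link{fit_quantile_model}}, but the log relative risk deviates
#' from the predictor by a zero-mean Gaussian error instead of the
#' asymmetric-Laplace quantile error, i.e. ordinary Bayesian disease-mapping
#' mean regression.  Quantile estimates from this model are read off the
#' posterior draws with \code{\link{mean_model_quantiles}}.
#'
#' @inheritParams fit_quantile_model
#' @return an \code{areal_fit} with \code{model = "mean"}.
#' @export
fit_mean_model <- function(panel, graph, config = model_config()) {
  fit_model_impl(panel, graph, config, "mean")
}

#' @export
print.areal_fit <- function(x, ...) {
  G <- nrow(x$chains[[1]]$z)
  cat(sprintf("areal_fit (%s model%s): %d regions x %d periods, %d chains x %d draws\n",
              x$model, if (x$model == "quantile") sprintf(", tau = %g", x$tau) else "",
              x$panel$n_regions, x$panel$n_times, length(x$chains), G))
  cat("max R-hat (monitored):", round(max(x$rhat), 3), "\n")
  invisible(x)
}

# all retained draws of one component, chains stacked row-wise
stack_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

#' Posterior draws of the relative-risk surface
#'
#' @param fit an \code{areal_fit}.
#' @return a (total retained draws) x (n regions * T periods) matrix of
#'   \eqn{\mu_{it}} draws, cells in column-major (region fastest) order.
#' @export
mu_draws <- function(fit) exp(stack_draws(fit, "z"))

#' Point estimate of the modeled quantile surface
#'
#' For the quantile model the \eqn{\tau}-quantile surface of relative risk
#' is \eqn{\hat Q_\tau(\mu_{it}) = \exp(\hat\eta_{\tau,it})}, the
#' exponentiated posterior point estimate of the linear predictor (the
#' error's \eqn{\tau}-quantile is zero by construction, so the predictor
#' alone carries the quantile).
#'
#' @param fit an \code{areal_fit} from \code{\link{fit_quantile_model}}.
#' @param point \code{"mean"} (default) or \code{"median"} posterior
#'   summary of \eqn{\eta}.
#' @return an \code{n x T} matrix of estimated quantile relative risks.
#' @export
estimate_quantile_surface <- function(fit, point = c("mean", "median")) {
  point <- match.arg(point)
  eta <- stack_draws(fit, "eta")
  est <- if (point == "mean") colMeans(eta)
         else apply(eta, 2, stats::median)
  matrix(exp(est), fit$panel$n_regions, fit$panel$n_times,
         dimnames = list(fit$panel$region_ids, fit$panel$times))
}

#' Empirical posterior quantiles of relative risk from the mean model
#'
#' The conventional route to a \eqn{\tau}-quantile surface: the empirical
#' \eqn{\tau}-quantile of the retained posterior \eqn{\mu_{it}} draws, per
#' space-time unit, using linear interpolation of order statistics
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param fit an \code{areal_fit} (normally from \code{\link{fit_mean_model}}).
#' @param tau quantile level in (0,1).
#' @return an \code{n x T} matrix.
#' @export
mean_model_quantiles <- function(fit, tau) {
  if (tau <= 0 || tau >= 1) stop("'tau' must lie in (0, 1)", call. = FALSE)
  md <- mu_draws(fit)
  q <- apply(md, 2, stats::quantile, probs = tau, type = 7, names = FALSE)
  matrix(q, fit$panel$n_regions, fit$panel$n_times,
         dimnames = list(fit$panel$region_ids, fit$panel$times))
}

# R-hat over the monitored scalars: the five SDs, the surface-average
# linear predictor, and regression coefficients if present.
monitored_rhat <- function(fit) {
  mon <- list()
  for (k in colnames(fit$chains[[1]]$sd))
    mon[[k]] <- lapply(fit$chains, function(ch) ch$sd[, k])
  mon[["eta_bar"]] <- lapply(fit$chains, function(ch) rowMeans(ch$eta))
  if (!is.null(fit$chains[[1]]$beta))
    for (k in seq_len(ncol(fit$chains[[1]]$beta)))
      mon[[paste0("beta", k)]] <- lapply(fit$chains, function(ch) ch$beta[, k])
  vapply(mon, function(ch) gelman_rhat(do.call(cbind, ch)), numeric(1))
}

#' Posterior summary table of a fit
#'
#' @param object an \code{areal_fit}.
#' @param ... unused.
#' @return a data frame with posterior mean, median, central 95\% interval
#'   and (for monitored scalars) R-hat, one row per monitored scalar and
#'   per relative-risk cell.
#' @export
summary.areal_fit <- function(object, ...) {
  sd_draws <- stack_draws(object, "sd")
  mu <- mu_draws(object)
  cells <- as.vector(outer(object$panel$region_ids, object$panel$times,
                           function(r, t) paste0("mu[", r, ":", t, "]")))
  colnames(mu) <- cells
  draws <- cbind(sd_draws, mu)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    lower95 = apply(draws, 2, stats::quantile, probs = 0.025, names = FALSE),
    upper95 = apply(draws, 2, stats::quantile, probs = 0.975, names = FALSE),
    rhat = NA_real_, row.names = NULL)
  out$rhat <- unname(object$rhat[match(out$parameter, names(object$rhat))])
  out
}

#' Write retained draws and a summary table to delimited files
#'
#' One row per retained draw with a \code{chain} column, one column per
#' monitored scalar and relative-risk cell, plus a companion
#' \code{<stem>_summary.csv}.
#'
#' @param fit an \code{areal_fit}.
#' @param stem output path stem; writes \code{<stem>_draws.csv} and
#'   \code{<stem>_summary.csv}.
#' @export
write_fit <- function(fit, stem) {
  per_chain <- lapply(seq_along(fit$chains), function(ci) {
    ch <- fit$chains[[ci]]
    mu <- exp(ch$z)
    colnames(mu) <- as.vector(outer(fit$panel$region_ids, fit$panel$times,
                                    function(r, t) paste0("mu[", r, ":", t, "]")))
    data.frame(chain = ci, ch$sd, mu, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, per_chain), paste0(stem, "_draws.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(summary(fit), paste0(stem, "_summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(stem)
}
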