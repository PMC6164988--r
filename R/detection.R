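#' Monte-Carlo exceedence probability
#'
#' The standard model-based cluster/hot-spot signal in disease mapping: per
#' space-time unit, the posterior probability that relative risk meets or
#' exceeds a cut-off \eqn{c}, estimated as the fraction of retained MCMC
#' draws at or above it,
#' \eqn{\hat P(\mu_{it} \ge c) = \sum_g I(\mu_{it}^{(g)} \ge c)/G}
#' (inclusive inequality).  Typical cut-offs are \eqn{c = 1} (null risk)
#' and \eqn{c = 2} (doubled risk); larger \eqn{c} means a more extreme
#' criterion, and the probability is nonincreasing in \eqn{c}.
#'
#' @param fit an \code{areal_fit}, or a numeric matrix of posterior
#'   relative-risk draws (rows = draws, columns = space-time units).
#' @param c relative-risk cut-off, > 0.
#' @return an object of class \code{exceedence_surface}: the probability
#'   matrix (regions x periods when a fit is supplied), the cut-off and the
#'   estimator label.
#' @export
exceedence_mc <- function(fit, c = 1) {
  if (c <= 0) stop("'c' must be > 0", call. = FALSE)
  if (inherits(fit, "areal_fit")) {
    md <- mu_draws(fit)
    prob <- matrix(colMeans(md >= c), fit$panel$n_regions, fit$panel$n_times,
                   dimnames = list(fit$panel$region_ids, fit$panel$times))
  } else {
    md <- as.matrix(fit)
    if (!nrow(md)) stop("no posterior draws supplied", call. = FALSE)
    prob <- matrix(colMeans(md >= c), nrow = 1,
                   dimnames = list(NULL, colnames(md)))
  }
  structure(list(prob = prob, c = c, source = "monte_carlo"),
            class = "exceedence_surface")
}

#' @export
print.exceedence_surface <- function(x, ...) {
  cat(sprintf("exceedence_surface (%s, c = %g): %d unit(s), range [%.3f, %.3f]\n",
              x$source, x$c, length(x$prob), min(x$prob), max(x$prob)))
  invisible(x)
}

#' Quantile-level exceedence probability
#'
#' Reformulates exceedence detection as quantile estimation: fixing the
#' quantile location of log relative risk at \eqn{\log c} via
#' \eqn{\log c = \log\mu_{it} + \epsilon_{\tau,it}} and treating the
#' quantile level itself as unknown, the defining constraint
#' \eqn{P(\epsilon_{\tau,it} \le 0) = \tau_{it}} makes the per-unit level
#' exactly the exceedence probability: \eqn{\tau_{it} = P(c \le \mu_{it})}.
#' Each \eqn{\tau_{it}} carries a flat Beta(1,1) prior; the error scale is
#' treated exactly as in the main quantile model — fixed at
#' \code{config$ll_scale} (default 1) or, when that is \code{NA}, sampled
#' under \code{Unif(0, sd_prior_upper)}.  The constraint replaces the
#' linear predictor, so no further random-effect structure enters.  Fitted
#' by the same adaptive Metropolis-within-Gibbs machinery, with the level
#' updated on the logit scale.
#'
#' Because each unit contributes a single residual to its own level, the
#' posterior of \eqn{\tau_{it}} is deliberately conservative: it pulls
#' probabilities away from 0 and 1 relative to the Monte-Carlo estimator
#' while preserving their ordering.  This damping of extreme tail
#' probabilities is the practical argument for the estimator over
#' mean-regression exceedence, which tends to saturate.
#'
#' @param panel a \code{\link{panel_data}}.
#' @param graph a \code{\link{region_graph}} over the same regions (used
#'   for validation and labeling).
#' @param c relative-risk cut-off, > 0 (typically 1 or 2).
#' @param config a \code{\link{model_config}}; its \code{tau} is ignored
#'   (the level is estimated), the MCMC settings and prior bound apply.
#' @param point posterior point summary of \eqn{\tau_{it}} to report.
#' @return an \code{exceedence_surface} with \code{source =
#'   "quantile_level"}; the fitted draws are attached as \code{tau_draws}.
#' @export
exceedence_quantile_level <- function(panel, graph, c = 1,
                                      config = model_config(),
                                      point = c("mean", "median")) {
  point <- match.arg(point)
  if (c <= 0) stop("'c' must be > 0", call. = FALSE)
  if (!inherits(panel, "panel_data")) stop("'panel' must be a panel_data",
                                           call. = FALSE)
  if (!identical(panel$region_ids, graph$region_ids))
    stop("panel regions and graph regions do not match", call. = FALSE)
  n <- panel$n_regions; nt <- panel$n_times; ncell <- n * nt
  y <- panel$y; e <- panel$e
  logc <- base::log(c)
  fixed_scale <- !is.na(config$ll_scale)
  chains <- lapply(seq_len(config$chains), function(ch) {
    chain_seed <- config$seed * 1000L + 911L * ch
    with_seed(chain_seed, {
      z <- base::log((y + 0.5) / e) +
        matrix(rnorm(ncell, sd = 0.2 * ch), n, nt)
      ltau <- matrix(rnorm(ncell, sd = 0.5), n, nt)   # logit of tau_it
      sd_e <- if (fixed_scale) config$ll_scale else runif(1, 0.3, 2)
      s_z <- matrix(0.5, n, nt); s_t <- matrix(0.8, n, nt); s_sd <- 0.3
      n_keep <- (config$iterations - config$burn_in) %/% config$thin
      out_tau <- matrix(NA_real_, n_keep, ncell)
      out_sd <- numeric(n_keep)
      keep <- 0L
      # AL log-density of the error log(c) - z at per-unit level tau
      al_ll <- function(z, ltau, s) {
        tau <- plogis(ltau)
        base::log(tau) + base::log1p(-tau) - base::log(s) -
          check_loss(logc - z, plogis(ltau)) / s
      }
      for (it in seq_len(config$iterations)) {
        adapting <- it <= config$burn_in
        gam <- if (adapting) min(0.25, 3 / sqrt(it)) else 0
        zp <- z + s_z * matrix(rnorm(ncell), n, nt)
        lr <- (y * zp - e * exp(zp) + al_ll(zp, ltau, sd_e)) -
              (y * z  - e * exp(z)  + al_ll(z,  ltau, sd_e))
        acc <- matrix(base::log(runif(ncell)), n, nt) < lr
        z[acc] <- zp[acc]
        if (adapting) s_z <- s_z * exp(gam * (acc - 0.44))

        # flat Beta(1,1) prior on tau; the logit-scale walk needs the
        # Jacobian log tau(1-tau)
        ltp <- ltau + s_t * matrix(rnorm(ncell), n, nt)
        lr <- al_ll(z, ltp, sd_e) - al_ll(z, ltau, sd_e) +
          base::log(plogis(ltp)) + base::log1p(-plogis(ltp)) -
          base::log(plogis(ltau)) - base::log1p(-plogis(ltau))
        acc <- matrix(base::log(runif(ncell)), n, nt) < lr
        ltau[acc] <- ltp[acc]
        if (adapting) s_t <- s_t * exp(gam * (acc - 0.44))

        sp <- if (fixed_scale) config$sd_prior_upper else sd_e * exp(s_sd * rnorm(1))
        if (sp < config$sd_prior_upper) {
          lr <- sum(al_ll(z, ltau, sp) - al_ll(z, ltau, sd_e)) +
            base::log(sp) - base::log(sd_e)
          acc1 <- base::log(runif(1)) < lr
        } else acc1 <- FALSE
        if (acc1) sd_e <- sp
        if (adapting) s_sd <- s_sd * exp(gam * (acc1 - 0.44))

        if (it > config$burn_in &&
            (it - config$burn_in) %% config$thin == 0) {
          keep <- keep + 1L
          out_tau[keep, ] <- plogis(ltau)
          out_sd[keep] <- sd_e
        }
      }
      list(tau = out_tau, sd = out_sd)
    })
  })
  tau_draws <- do.call(rbind, lapply(chains, `[[`, "tau"))
  rh <- c(sd_err = gelman_rhat(do.call(cbind, lapply(chains, `[[`, "sd"))),
          tau_bar = gelman_rhat(do.call(cbind, lapply(chains, function(ch)
            rowMeans(ch$tau)))))
  if (any(rh > 1.1))
    warning("convergence not reached (R-hat > 1.1) for: ",
            paste(sprintf("%s=%.3f", names(rh[rh > 1.1]), rh[rh > 1.1]),
                  collapse = ", "), call. = FALSE)
  est <- if (point == "mean") colMeans(tau_draws)
         else apply(tau_draws, 2, stats::median)
  structure(list(prob = matrix(est, n, nt,
                               dimnames = list(panel$region_ids, panel$times)),
                 c = c, source = "quantile_level",
                 tau_draws = tau_draws, rhat = rh),
            class = "exceedence_surface")
}

#' Flag adverse-risk units
#'
#' Thresholds an exceedence surface at a conventional probability cut-off
#' (0.95, 0.975 or 0.99 are common choices): units whose exceedence
#' probability meets or exceeds the threshold are flagged as adverse
#' (hot spots / cluster members).
#'
#' @param surface an \code{\link{exceedence_mc}} /
#'   \code{\link{exceedence_quantile_level}} result.
#' @param prob_threshold probability cut-off in (0,1), default 0.95.
#' @return a list with the logical \code{flag} matrix and \code{n_flagged}.
#' @export
classify_adverse <- function(surface, prob_threshold = 0.95) {
  if (!inherits(surface, "exceedence_surface"))
    stop("'surface' must be an exceedence_surface", call. = FALSE)
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("'prob_threshold' must lie in (0, 1)", call. = FALSE)
  flag <- surface$prob >= prob_threshold
  list(flag = flag, n_flagged = sum(flag),
       prob_threshold = prob_threshold, c = surface$c)
}

#' Write an exceedence surface as a delimited table
#'
#' One row per space-time unit: region, time, cut-off, probability and the
#' adverse flag at the supplied probability threshold.
#'
#' @param surface an \code{exceedence_surface}.
#' @param path output path.
#' @param prob_threshold flagging threshold passed to
#'   \code{\link{classify_adverse}}.
#' @export
write_exceedence <- function(surface, path, prob_threshold = 0.95) {
  pr <- surface$prob
  rid <- rownames(pr); if (is.null(rid)) rid <- as.character(seq_len(nrow(pr)))
  tid <- colnames(pr); if (is.null(tid)) tid <- as.character(seq_len(ncol(pr)))
  grid <- expand.grid(ri = seq_len(nrow(pr)), ti = seq_len(ncol(pr)))
  df <- data.frame(region_id = rid[grid$ri], time = tid[grid$ti],
                   c = surface$c,
                   probability = pr[cbind(grid$ri, grid$ti)],
                   flag = pr[cbind(grid$ri, grid$ti)] >= prob_threshold,
                   source = surface$source)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
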