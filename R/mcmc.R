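# Internal MCMC engine shared by the quantile (asymmetric-Laplace error)
# and mean (Gaussian error) models.
#
# Update scheme, one sweep:
#   z      log relative risk, elementwise Metropolis (conditionally
#          independent cells given eta)
#   theta  space-time interaction; quantile model: elementwise Metropolis
#          plus a global non-centered rescale move; mean model: conjugate
#          Gibbs (normal-normal)
#   v      exchangeable spatial effect; Metropolis (quantile) / Gibbs (mean)
#   u      ICAR effect, updated over graph color classes (no two adjacent
#          regions in a class, so neighbor sums stay fixed within a block);
#          Metropolis (quantile) / Gibbs (mean); afterwards re-centered to
#          mean zero with the level moved into lambda, leaving eta unchanged
#   u/v    exchange move shifting shares between the confounded BYM
#          components at fixed sum (prior-only ratio; quantile model)
#   lambda RW1 trend over even/odd periods; Metropolis (quantile) / Gibbs
#          (mean)
#   beta   regression coefficients, elementwise Metropolis
#   sd_*   standard deviations, random-walk on the log scale with Jacobian,
#          hard rejection outside (0, sd_upper); the AL scale is skipped
#          when fixed
#
# Metropolis proposal scales adapt per scalar during burn-in by a
# Robbins-Monro recursion targeting 0.44 (0.234 for joint moves), then
# freeze so the retained draws come from a fixed transition kernel.

run_chain <- function(y, e, X, pre, model, tau, sd_upper, iters, burnin,
                      thin, chain_seed, start, beta_prior_sd = 100,
                      ll_scale = NA) {
  n <- nrow(y); nt <- ncol(y); ncell <- n * nt
  p <- if (is.null(X)) 0L else dim(X)[3]
  quantile_model <- identical(model, "quantile")
  fixed_scale <- quantile_model && !is.na(ll_scale)

  # unnormalized error log-density of residual r = z - eta
  err_ll <- if (quantile_model) {
    function(r, s) -base::log(s) - check_loss(r, tau) / s
  } else {
    function(r, s) -base::log(s) - r * r / (2 * s * s)
  }

  rw1_ll <- function(lam, s) {
    # lambda_1 anchored at zero; increments N(0, s^2)
    -nt * base::log(s) - (lam[1]^2 + if (nt > 1) sum(diff(lam)^2) else 0) / (2 * s * s)
  }

  with_seed(chain_seed, {
    z <- start$z; u <- start$u; v <- start$v
    lam <- start$lam; theta <- start$theta; beta <- start$beta
    sd_u <- start$sd_u; sd_v <- start$sd_v; sd_l <- start$sd_l
    sd_t <- start$sd_t
    sd_e <- if (fixed_scale) ll_scale else start$sd_e

    xb <- matrix(0, n, nt)
    if (p > 0) for (k in seq_len(p)) xb <- xb + X[, , k] * beta[k]
    eta <- xb + outer(u + v, rep(1, nt)) +
      matrix(lam, n, nt, byrow = TRUE) + theta

    # adaptive proposal scales
    s_z <- matrix(0.5, n, nt); s_th <- matrix(0.5, n, nt)
    s_u <- rep(0.5, n); s_v <- rep(0.5, n); s_lam <- rep(0.5, nt)
    s_beta <- rep(0.1, max(p, 1)); s_sd <- rep(0.3, 5)
    s_uv <- 0.5; s_thr <- 0.2

    n_keep <- (iters - burnin) %/% thin
    out_z <- matrix(NA_real_, n_keep, ncell)
    out_eta <- matrix(NA_real_, n_keep, ncell)
    out_u <- matrix(NA_real_, n_keep, n)
    out_v <- matrix(NA_real_, n_keep, n)
    out_lam <- matrix(NA_real_, n_keep, nt)
    out_sd <- matrix(NA_real_, n_keep, 5)
    out_beta <- if (p > 0) matrix(NA_real_, n_keep, p) else NULL
    keep_row <- 0L

    colors <- pre$colors
    edge_i <- pre$edge_mat[, 1]; edge_j <- pre$edge_mat[, 2]
    deg <- pre$n_neighbors
    nbr_sum <- function(u) {
      if (!length(edge_i)) return(numeric(n))
      tapply_sum(c(edge_i, edge_j), c(u[edge_j], u[edge_i]), n)
    }

    for (it in seq_len(iters)) {
      adapting <- it <= burnin
      gam <- if (adapting) min(0.25, 3 / sqrt(it)) else 0

      ## --- z | rest -----------------------------------------------------
      zp <- z + s_z * matrix(rnorm(ncell), n, nt)
      lr <- (y * zp - e * exp(zp) + err_ll(zp - eta, sd_e)) -
            (y * z  - e * exp(z)  + err_ll(z  - eta, sd_e))
      acc <- matrix(base::log(runif(ncell)), n, nt) < lr
      z[acc] <- zp[acc]
      if (adapting) s_z <- s_z * exp(gam * (acc - 0.44))

      ## --- theta | rest -------------------------------------------------
      if (quantile_model) {
        thp <- theta + s_th * matrix(rnorm(ncell), n, nt)
        d <- thp - theta
        lr <- err_ll(z - eta - d, sd_e) - err_ll(z - eta, sd_e) +
          (theta * theta - thp * thp) / (2 * sd_t * sd_t)
        acc <- matrix(base::log(runif(ncell)), n, nt) < lr
        theta[acc] <- thp[acc]
        eta[acc] <- eta[acc] + d[acc]
        if (adapting) s_th <- s_th * exp(gam * (acc - 0.44))

        # global non-centered rescale: multiplies the whole interaction
        # surface so its magnitude and sd_theta traverse the funnel;
        # Jacobian ncell * log c
        cfac <- exp(s_thr * rnorm(1))
        d <- (cfac - 1) * theta
        r <- z - eta
        lr <- sum(err_ll(r - d, sd_e) - err_ll(r, sd_e)) +
          (1 - cfac * cfac) * sum(theta * theta) / (2 * sd_t * sd_t) +
          ncell * base::log(cfac)
        if (base::log(runif(1)) < lr) {
          theta <- cfac * theta
          eta <- eta + d
          acc1 <- TRUE
        } else acc1 <- FALSE
        if (adapting) s_thr <- s_thr * exp(gam * (acc1 - 0.234))
      } else {
        # conjugate Gibbs: residual with theta removed is Gaussian
        w <- z - eta + theta
        prec <- 1 / (sd_e * sd_e) + 1 / (sd_t * sd_t)
        thp <- rnorm(ncell, mean = (w / (sd_e * sd_e)) / prec,
                     sd = sqrt(1 / prec))
        thp <- matrix(thp, n, nt)
        eta <- eta + (thp - theta)
        theta <- thp
      }

      ## --- v | rest (regions are conditionally independent) -------------
      if (quantile_model) {
        vp <- v + s_v * rnorm(n)
        d <- vp - v
        r <- z - eta
        lr <- rowSums(err_ll(r - d, sd_e) - err_ll(r, sd_e)) +
          (v * v - vp * vp) / (2 * sd_v * sd_v)
        acc <- base::log(runif(n)) < lr
        v[acc] <- vp[acc]
        eta[acc, ] <- eta[acc, , drop = FALSE] + d[acc]
        if (adapting) s_v <- s_v * exp(gam * (acc - 0.44))
      } else {
        w <- rowSums(z - eta) + nt * v
        prec <- nt / (sd_e * sd_e) + 1 / (sd_v * sd_v)
        vp <- rnorm(n, mean = (w / (sd_e * sd_e)) / prec, sd = sqrt(1 / prec))
        eta <- eta + (vp - v)
        v <- vp
      }

      ## --- u | rest, by color class -------------------------------------
      for (cls in colors) {
        if (quantile_model) {
          up_all <- u
          up_all[cls] <- u[cls] + s_u[cls] * rnorm(length(cls))
          d <- up_all[cls] - u[cls]
          r <- (z - eta)[cls, , drop = FALSE]
          nsum <- nbr_sum(u)[cls]
          icar <- -(deg[cls] * (up_all[cls]^2 - u[cls]^2) -
                      2 * nsum * d) / (2 * sd_u * sd_u)
          lr <- rowSums(err_ll(r - d, sd_e) - err_ll(r, sd_e)) + icar
          acc <- base::log(runif(length(cls))) < lr
          ai <- cls[acc]
          u[ai] <- up_all[ai]
          eta[ai, ] <- eta[ai, , drop = FALSE] + d[acc]
          if (adapting) s_u[cls] <- s_u[cls] * exp(gam * (acc - 0.44))
        } else {
          w <- rowSums((z - eta)[cls, , drop = FALSE]) + nt * u[cls]
          nsum <- nbr_sum(u)[cls]
          prec <- deg[cls] / (sd_u * sd_u) + nt / (sd_e * sd_e)
          mean_post <- (nsum / (sd_u * sd_u) + w / (sd_e * sd_e)) / prec
          up <- rnorm(length(cls), mean = mean_post, sd = sqrt(1 / prec))
          eta[cls, ] <- eta[cls, , drop = FALSE] + (up - u[cls])
          u[cls] <- up
        }
      }
      # identification: project out the ICAR level, keeping eta fixed by
      # moving the level into the random-walk trend
      m <- mean(u)
      u <- u - m
      lam <- lam + m

      ## --- u/v exchange: shift shares between the confounded structured
      ## and unstructured effects at fixed sum (eta unchanged, prior-only
      ## ratio); mixes the BYM decomposition ------------------------------
      {
        d <- s_uv * rnorm(n)
        up <- u + d; vp <- v - d
        um <- mean(up); up <- up - um; vp <- vp + um   # keep u centered
        quad_old <- sum(deg * u * u) - sum(u * nbr_sum(u))
        quad_new <- sum(deg * up * up) - sum(up * nbr_sum(up))
        lr <- -(quad_new - quad_old) / (2 * sd_u * sd_u) +
          sum(v * v - vp * vp) / (2 * sd_v * sd_v)
        if (base::log(runif(1)) < lr) {
          u <- up; v <- vp
          acc1 <- TRUE
        } else acc1 <- FALSE
        if (adapting) s_uv <- s_uv * exp(gam * (acc1 - 0.234))
      }

      ## --- lambda | rest, by parity -------------------------------------
      for (par in list(seq(1, nt, by = 2), if (nt > 1) seq(2, nt, by = 2))) {
        if (is.null(par) || !length(par)) next
        if (quantile_model) {
          lp_all <- lam
          lp_all[par] <- lam[par] + s_lam[par] * rnorm(length(par))
          d <- lp_all[par] - lam[par]
          r <- (z - eta)[, par, drop = FALSE]
          dr <- matrix(d, n, length(par), byrow = TRUE)
          lrw <- vapply(seq_along(par), function(k) {
            new <- lam; new[par[k]] <- lp_all[par[k]]
            rw1_ll(new, sd_l) - rw1_ll(lam, sd_l)
          }, numeric(1))
          lr <- colSums(err_ll(r - dr, sd_e) - err_ll(r, sd_e)) + lrw
          acc <- base::log(runif(length(par))) < lr
          ai <- par[acc]
          lam[ai] <- lp_all[ai]
          eta[, ai] <- eta[, ai, drop = FALSE] +
            matrix(d[acc], n, length(ai), byrow = TRUE)
          if (adapting) s_lam[par] <- s_lam[par] * exp(gam * (acc - 0.44))
        } else {
          for (t in par) {
            # RW1 neighbors of period t (plus the t = 1 zero anchor)
            anchors <- c(if (t == 1) 0 else lam[t - 1],
                         if (t < nt) lam[t + 1])
            prior_prec <- length(anchors) / (sd_l * sd_l)
            w <- sum(z[, t] - eta[, t]) + n * lam[t]
            prec <- prior_prec + n / (sd_e * sd_e)
            mean_post <- (sum(anchors) / (sd_l * sd_l) +
                            w / (sd_e * sd_e)) / prec
            lt <- rnorm(1, mean = mean_post, sd = sqrt(1 / prec))
            eta[, t] <- eta[, t] + (lt - lam[t])
            lam[t] <- lt
          }
        }
      }

      ## --- beta | rest ---------------------------------------------------
      if (p > 0) {
        for (k in seq_len(p)) {
          bp <- beta[k] + s_beta[k] * rnorm(1)
          d <- (bp - beta[k]) * X[, , k]
          r <- z - eta
          lr <- sum(err_ll(r - d, sd_e) - err_ll(r, sd_e)) +
            (beta[k]^2 - bp^2) / (2 * beta_prior_sd^2)
          if (base::log(runif(1)) < lr) {
            beta[k] <- bp
            eta <- eta + d
            acc1 <- TRUE
          } else acc1 <- FALSE
          if (adapting) s_beta[k] <- s_beta[k] * exp(gam * (acc1 - 0.44))
        }
      }

      ## --- standard deviations | rest ------------------------------------
      su_quad <- if (length(edge_i)) sum((u[edge_i] - u[edge_j])^2) else 0
      sd_ll <- list(
        function(s) -(n - 1) * base::log(s) - su_quad / (2 * s * s),
        function(s) -n * base::log(s) - sum(v * v) / (2 * s * s),
        function(s) rw1_ll(lam, s),
        function(s) -ncell * base::log(s) - sum(theta * theta) / (2 * s * s),
        function(s) sum(err_ll(z - eta, s))
      )
      sds <- c(sd_u, sd_v, sd_l, sd_t, sd_e)
      for (k in if (fixed_scale) 1:4 else 1:5) {
        sp <- sds[k] * exp(s_sd[k] * rnorm(1))
        # 1e-8 is a numerical floor, orders of magnitude below any
        # statistically meaningful scale; it stops the degenerate drift of
        # an unidentified scale (e.g. one region, one effect) to underflow
        if (sp > 1e-8 && sp < sd_upper) {
          lr <- sd_ll[[k]](sp) - sd_ll[[k]](sds[k]) +
            base::log(sp) - base::log(sds[k])   # Jacobian of the log walk
          acc1 <- is.finite(lr) && base::log(runif(1)) < lr
        } else acc1 <- FALSE
        if (acc1) sds[k] <- sp
        # clamp keeps a flat conditional (e.g. the ICAR scale with a single
        # region) from running the adapted step to under/overflow
        if (adapting)
          s_sd[k] <- min(5, max(1e-3, s_sd[k] * exp(gam * (acc1 - 0.44))))
      }
      sd_u <- sds[1]; sd_v <- sds[2]; sd_l <- sds[3]
      sd_t <- sds[4]; sd_e <- sds[5]

      ## --- retain ---------------------------------------------------------
      if (it > burnin && (it - burnin) %% thin == 0) {
        keep_row <- keep_row + 1L
        out_z[keep_row, ] <- z
        out_eta[keep_row, ] <- eta
        out_u[keep_row, ] <- u
        out_v[keep_row, ] <- v
        out_lam[keep_row, ] <- lam
        out_sd[keep_row, ] <- sds
        if (p > 0) out_beta[keep_row, ] <- beta
      }
    }

    colnames(out_sd) <- c("sd_u", "sd_v", "sd_lambda", "sd_theta", "sd_err")
    list(z = out_z, eta = out_eta, u = out_u, v = out_v, lam = out_lam,
         sd = out_sd, beta = out_beta)
  })
}

# grouped sum by integer index without factor overhead
tapply_sum <- function(idx, val, n) {
  s <- numeric(n)
  o <- order(idx)
  idx <- idx[o]; val <- val[o]
  cs <- cumsum(val)
  last <- c(idx[-1] != idx[-length(idx)], TRUE)
  tot <- cs[last]
  tot <- c(tot[1], diff(tot))
  s[idx[last]] <- tot
  s
}

# Overdispersed chain starts around crude empirical values.
chain_start <- function(y, e, X, n, nt, p, sd_upper, chain) {
  jitter_sd <- 0.2 + 0.2 * (chain - 1)
  z <- base::log((y + 0.5) / e) + matrix(rnorm(n * nt, sd = jitter_sd), n, nt)
  list(z = z,
       u = rnorm(n, sd = 0.1),
       v = rnorm(n, sd = 0.1),
       lam = rnorm(nt, sd = 0.1),
       theta = matrix(rnorm(n * nt, sd = 0.1), n, nt),
       beta = if (p > 0) rnorm(p, sd = 0.1) else numeric(0),
       sd_u = runif(1, 0.3, min(3, sd_upper)),
       sd_v = runif(1, 0.1, min(1, sd_upper)),
       sd_l = runif(1, 0.1, min(1, sd_upper)),
       sd_t = runif(1, 0.1, min(1, sd_upper)),
       sd_e = runif(1, 0.3, min(2, sd_upper)))
}
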