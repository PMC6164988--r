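#' Mean squared error between estimated and true surfaces
#'
#' Squared error between an estimated quantile (or risk) surface and its
#' known truth, aggregated over all space-time units.  Both the per-unit
#' mean and the total are exposed, because MSE totals reported for
#' spatiotemporal simulation studies are often on the summed scale.
#'
#' @param estimate,truth numeric matrices/vectors of identical shape.
#' @param aggregation \code{"mean"} (default, per-unit average) or
#'   \code{"sum"} (total over units).
#' @return nonnegative scalar.
#' @export
mse_surface <- function(estimate, truth, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  if (!identical(dim(as.matrix(estimate)), dim(as.matrix(truth))))
    stop("'estimate' and 'truth' shapes differ", call. = FALSE)
  se <- (as.numeric(estimate) - as.numeric(truth))^2
  if (aggregation == "mean") mean(se) else sum(se)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic two-stage between/within-chain diagnostic: with \eqn{m}
#' chains of length \eqn{n}, within-chain variance \eqn{W} (mean of the
#' per-chain sample variances) and between-chain variance \eqn{B/n} (the
#' sample variance of the chain means), the pooled posterior-variance
#' estimate is \eqn{\hat V = (n-1)/n\, W + B/n} and
#' \eqn{\hat R = \sqrt{\hat V / W}}.  Values near 1 indicate the chains
#' are sampling the same distribution; the conventional mixing threshold
#' used throughout this package is 1.1.  Chains that are all identical
#' constants (zero within-variance) return 1 by convention.
#'
#' @param chains a numeric matrix with one column per chain (equal
#'   lengths, >= 2 draws), or a list of equal-length numeric vectors.
#' @return scalar \eqn{\hat R}.
#' @export
gelman_rhat <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1)
      stop("chains must have equal length", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2)
    stop("R-hat needs at least 2 chains; rerun with chains >= 2", call. = FALSE)
  if (n < 2) stop("chains must contain at least 2 draws", call. = FALSE)
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Simulation-study model comparison
#'
#' Runs the full evaluation protocol on replicate synthetic data sets: per
#' replicate, fit the quantile model at each requested level
#' (\code{\link{fit_quantile_model}}, surface via
#' \code{\link{estimate_quantile_surface}}) and the mean comparator once
#' (\code{\link{fit_mean_model}}, surfaces via
#' \code{\link{mean_model_quantiles}}), score both against the replicate's
#' analytic true quantile surfaces with \code{\link{mse_surface}}, and
#' aggregate across replicates.  Fit failures are recorded per replicate
#' and excluded from the aggregate rather than aborting the study.
#'
#' @param study a \code{\link{sim_study}} from \code{\link{simulate_counts}}.
#' @param tau_levels quantile levels to evaluate; defaults to the study's.
#' @param config a \code{\link{model_config}} template for the fits (its
#'   \code{tau} and \code{seed} are overridden per level / replicate).
#' @param aggregation MSE aggregation rule, see \code{\link{mse_surface}}.
#' @param verbose print per-replicate progress.
#' @return an object of class \code{evaluation_report}: per-replicate MSE
#'   tables, aggregated MSE per model and level, their ratio, the replicate
#'   count and the max observed R-hat.
#' @export
compare_models <- function(study, tau_levels = NULL,
                           config = model_config(),
                           aggregation = c("mean", "sum"),
                           verbose = FALSE) {
  aggregation <- match.arg(aggregation)
  if (!inherits(study, "sim_study")) stop("'study' must be a sim_study",
                                          call. = FALSE)
  if (is.null(tau_levels)) tau_levels <- study$config$tau_levels
  graph <- study$config$graph
  rows <- list(); max_rhat <- -Inf; failures <- character(0)
  for (r in seq_along(study$replicates)) {
    rep_r <- study$replicates[[r]]
    res <- tryCatch({
      cfg_mean <- config
      cfg_mean$seed <- config$seed + 10000L * r
      mean_fit <- fit_mean_model(rep_r$panel, graph, cfg_mean)
      max_rhat <- max(max_rhat, mean_fit$rhat)
      out <- NULL
      for (tl in tau_levels) {
        truth <- rep_r$truth$Q[[format(tl)]]
        if (is.null(truth))
          truth <- exp(rep_r$truth$eta +
                         qt(tl, study$config$error_df) *
                         sqrt((study$config$error_df - 2) / study$config$error_df))
        cfg_q <- config
        cfg_q$tau <- tl
        cfg_q$seed <- config$seed + 10000L * r + round(1000 * tl)
        q_fit <- fit_quantile_model(rep_r$panel, graph, cfg_q)
        max_rhat <- max(max_rhat, q_fit$rhat)
        out <- rbind(out, data.frame(
          replicate = r, tau = tl,
          mse_quantile = mse_surface(estimate_quantile_surface(q_fit),
                                     truth, aggregation),
          mse_mean = mse_surface(mean_model_quantiles(mean_fit, tl),
                                 truth, aggregation)))
      }
      out
    }, error = function(err) {
      failures <<- c(failures, sprintf("replicate %d: %s", r,
                                       conditionMessage(err)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
    if (verbose) message("replicate ", r, " done")
  }
  if (!length(rows)) stop("all replicate fits failed", call. = FALSE)
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$tau), function(d)
    data.frame(tau = d$tau[1],
               mse_quantile = mean(d$mse_quantile),
               mse_mean = mean(d$mse_mean),
               ratio_mean_over_quantile = mean(d$mse_mean) / mean(d$mse_quantile),
               quantile_wins = sum(d$mse_quantile < d$mse_mean),
               n_replicates = nrow(d))))
  rownames(agg) <- NULL
  structure(list(per_replicate = per_rep, aggregate = agg,
                 aggregation = aggregation, failures = failures,
                 max_rhat = max_rhat),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (MSE aggregation:", x$aggregation, ")\n")
  print(x$aggregate, row.names = FALSE)
  if (length(x$failures))
    cat("failed replicates:\n ", paste(x$failures, collapse = "\n  "), "\n")
  cat("max monitored R-hat across fits:", round(x$max_rhat, 3), "\n")
  invisible(x)
}

#' Write an evaluation report to delimited tables
#'
#' @param report an \code{evaluation_report}.
#' @param stem output path stem; writes \code{<stem>_replicates.csv} and
#'   \code{<stem>_aggregate.csv}.
#' @export
write_report <- function(report, stem) {
  utils::write.table(report$per_replicate, paste0(stem, "_replicates.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(report$aggregate, paste0(stem, "_aggregate.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(stem)
}
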