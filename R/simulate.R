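#' Draw from the intrinsic CAR distribution on a connected graph
#'
#' Samples the intrinsic conditional autoregressive (ICAR) law with
#' conditional specification \eqn{u_i | u_{-i} \sim
#' N(\bar u_{\delta i}, \sigma_u^2 / n_{\delta i})}, realized under the
#' sum-to-zero constraint that removes the improper level.  The draw is
#' exact: the joint ICAR density is \eqn{\propto \exp\{-u^\top Q u /
#' (2\sigma_u^2)\}} with \eqn{Q} the graph Laplacian, so a constrained draw
#' is \eqn{u = \sigma_u \sum_k \lambda_k^{-1/2} z_k v_k} over the non-null
#' eigenpairs \eqn{(\lambda_k, v_k)} of \eqn{Q}, with \eqn{z_k} standard
#' normal.  The constrained covariance is \eqn{\sigma_u^2 Q^{+}} (the
#' Moore-Penrose pseudo-inverse).
#'
#' @param graph a connected \code{\link{region_graph}}.
#' @param variance the ICAR variance \eqn{\sigma_u^2} (> 0).
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @return an \code{n x n_regions} matrix of draws (a vector if
#'   \code{n = 1}); each row sums to zero.
#' @export
sample_icar <- function(graph, variance, n = 1, seed = NULL) {
  stop_if_disconnected(graph)
  if (variance <= 0) stop("'variance' must be > 0", call. = FALSE)
  eg <- eigen(graph_laplacian(graph), symmetric = TRUE)
  nr <- graph$n_regions
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(!pos) != 1)
    stop("Laplacian null space is not one-dimensional; graph not connected",
         call. = FALSE)
  V <- eg$vectors[, pos, drop = FALSE]
  s <- sqrt(variance / eg$values[pos])
  draw <- function() {
    z <- matrix(rnorm(n * sum(pos)), n, sum(pos))
    u <- z %*% (t(V) * s)
    colnames(u) <- graph$region_ids
    if (n == 1) drop(u) else u
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Draw a first-order random-walk trend
#'
#' \eqn{\lambda_1 \sim N(0, \sigma_\lambda^2)} and
#' \eqn{\lambda_t | \lambda_{t-1} \sim N(\lambda_{t-1}, \sigma_\lambda^2)}
#' for \eqn{t \ge 2}, so the marginal variance grows linearly,
#' \eqn{Var(\lambda_t) = t\,\sigma_\lambda^2}.
#'
#' @param n_times number of periods (>= 1).
#' @param variance increment variance \eqn{\sigma_\lambda^2} (> 0).
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @return an \code{n x n_times} matrix (a vector if \code{n = 1}).
#' @export
sample_rw1 <- function(n_times, variance, n = 1, seed = NULL) {
  if (n_times < 1) stop("'n_times' must be >= 1", call. = FALSE)
  if (variance <= 0) stop("'variance' must be > 0", call. = FALSE)
  draw <- function() {
    z <- matrix(rnorm(n * n_times, sd = sqrt(variance)), n, n_times)
    lam <- t(apply(z, 1, cumsum))
    if (n_times == 1) lam <- matrix(z, n, 1)
    if (n == 1) drop(lam) else lam
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulation-study configuration
#'
#' Bundles the generative-process settings for
#' \code{\link{simulate_counts}}.  The defaults reproduce the study design
#' used throughout: 5 yearly periods; ICAR spatial variance 1; exchangeable
#' spatial, random-walk temporal, and interaction variances all 0.2;
#' quantile levels 0.9, 0.5, 0.1; 50 replicate data sets; log-scale errors
#' drawn from a unit-variance t distribution whose degrees of freedom equal
#' the region's expected count (so well-populated regions have near-Gaussian
#' errors and sparse regions heavy tails).  When \code{expected_counts} is
#' not supplied, per-region expected counts are drawn once, log-uniformly
#' between 20 and 2000, mimicking the spread of standardized expected counts
#' across counties of mixed population size.
#'
#' @param graph a connected \code{\link{region_graph}}.
#' @param n_times number of periods.
#' @param var_u,var_v,var_lambda,var_theta component variances (log scale).
#' @param expected_counts per-region expected counts \eqn{e_i} (> 0),
#'   constant over time; \code{NULL} draws the log-uniform default.
#' @param error_df per-region t degrees of freedom for the log-scale error;
#'   \code{NULL} uses \code{expected_counts} (the default rule).  Must
#'   exceed 2: the error is rescaled to unit variance, which does not exist
#'   otherwise.
#' @param tau_levels quantile levels at which true quantile surfaces are
#'   tabulated.
#' @param n_replicates number of replicate data sets.
#' @param seed integer seed controlling everything, including the default
#'   expected counts.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(graph, n_times = 5,
                       var_u = 1, var_v = 0.2, var_lambda = 0.2,
                       var_theta = 0.2,
                       expected_counts = NULL, error_df = NULL,
                       tau_levels = c(0.9, 0.5, 0.1),
                       n_replicates = 50, seed = 1) {
  stop_if_disconnected(graph)
  for (v in c(var_u, var_v, var_lambda, var_theta))
    if (!is.finite(v) || v <= 0) stop("variances must be > 0", call. = FALSE)
  if (n_times < 1 || n_replicates < 1)
    stop("'n_times' and 'n_replicates' must be >= 1", call. = FALSE)
  if (any(tau_levels <= 0) || any(tau_levels >= 1))
    stop("'tau_levels' must lie in (0, 1)", call. = FALSE)
  if (is.null(expected_counts)) {
    expected_counts <- with_seed(seed * 1000L + 379L,
                                 exp(runif(graph$n_regions, log(20), log(2000))))
  }
  if (length(expected_counts) != graph$n_regions || any(expected_counts <= 0))
    stop("'expected_counts' must be positive, one per region", call. = FALSE)
  if (is.null(error_df)) error_df <- expected_counts
  if (length(error_df) == 1) error_df <- rep(error_df, graph$n_regions)
  if (length(error_df) != graph$n_regions)
    stop("'error_df' must be scalar or one per region", call. = FALSE)
  if (any(error_df <= 2))
    stop("'error_df' must exceed 2: the log-scale error is standardized ",
         "to unit variance, and a t distribution with df <= 2 has none",
         call. = FALSE)
  structure(list(graph = graph, n_times = n_times,
                 var_u = var_u, var_v = var_v, var_lambda = var_lambda,
                 var_theta = var_theta,
                 expected_counts = expected_counts, error_df = error_df,
                 tau_levels = tau_levels, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate spatiotemporal count data with known quantile truth
#'
#' Generates replicate data sets from the full generative process: per
#' replicate, spatial effects \eqn{u} (ICAR) and \eqn{v} (exchangeable
#' Gaussian), a random-walk trend \eqn{\lambda}, and interaction
#' \eqn{\theta} form the linear predictor \eqn{\eta_{it} = u_i + v_i +
#' \lambda_t + \theta_{it}} (no intercept, no covariates); log-scale errors
#' \eqn{\epsilon_{it}} are drawn from a zero-center unit-variance t
#' distribution with region-specific degrees of freedom; the relative risk
#' is \eqn{\mu_{it} = \exp(\eta_{it} + \epsilon_{it})} and counts are
#' \eqn{y_{it} \sim Poisson(e_i \mu_{it})}.  The error law is deliberately
#' neither Gaussian nor Laplace, so neither the quantile model nor the
#' mean-regression comparator fits the truth exactly.
#'
#' True quantile surfaces are analytic: \eqn{Q_\tau(\mu_{it}) =
#' \exp\{\eta_{it} + F^{-1}_{t,df_i}(\tau)\sqrt{(df_i-2)/df_i}\}}, and at
#' \eqn{\tau = 0.5} the symmetric error makes this exactly
#' \eqn{\exp(\eta_{it})}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{sim_study}: a list with the
#'   \code{config} and \code{replicates}, each replicate holding the
#'   \code{panel} (a \code{\link{panel_data}}) and \code{truth} (list with
#'   \code{eta}, \code{mu}, \code{epsilon} and \code{Q}, the latter a named
#'   list of true quantile surfaces per requested tau).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config",
                                            call. = FALSE)
  g <- config$graph
  nr <- g$n_regions; nt <- config$n_times
  df <- config$error_df
  tscale <- sqrt((df - 2) / df)
  reps <- with_seed(config$seed, lapply(seq_len(config$n_replicates), function(r) {
    u <- as.numeric(sample_icar(g, config$var_u))
    v <- rnorm(nr, sd = sqrt(config$var_v))
    lam <- as.numeric(sample_rw1(nt, config$var_lambda))
    theta <- matrix(rnorm(nr * nt, sd = sqrt(config$var_theta)), nr, nt)
    eta <- outer(u + v, rep(1, nt)) + matrix(lam, nr, nt, byrow = TRUE) + theta
    eps <- matrix(rt(nr * nt, df = rep(df, nt)), nr, nt) * tscale
    mu <- exp(eta + eps)
    y <- matrix(rpois(nr * nt, lambda = rep(config$expected_counts, nt) * mu),
                nr, nt)
    Q <- lapply(config$tau_levels, function(tl)
      exp(eta + outer(qt(tl, df) * tscale, rep(1, nt))))
    names(Q) <- format(config$tau_levels)
    list(panel = panel_data(y, config$expected_counts,
                            region_ids = g$region_ids),
         truth = list(eta = eta, mu = mu, epsilon = eps,
                      u = u, v = v, lambda = lam, theta = theta, Q = Q))
  }))
  structure(list(config = config, replicates = reps), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", length(x$replicates), "replicate(s),",
      x$config$graph$n_regions, "regions x", x$config$n_times, "periods\n")
  invisible(x)
}

#' Endemic-window expected counts by internal standardization
#'
#' Computes per-region expected counts from an endemic (baseline) window of
#' the series itself, when no external standard population rates exist:
#' \deqn{e_i = pop_i \times \frac{\sum_i \sum_{t \in T_{en}} y_{it} /
#' |T_{en}|}{\sum_i pop_i},}
#' i.e. the study-region-wide average cases per period during the endemic
#' window, shared out proportionally to population.  The result is constant
#' over time and conserves mass: \eqn{\sum_i e_i} equals the window-average
#' total count per period.
#'
#' @param pop per-region populations at risk (> 0).
#' @param counts region-by-time count matrix covering the window.
#' @param endemic_window integer vector of column indices (time periods)
#'   forming the endemic window.
#' @return per-region expected counts \eqn{e_i}.
#' @export
expected_rates_endemic <- function(pop, counts, endemic_window) {
  counts <- as.matrix(counts)
  if (length(endemic_window) < 1) stop("endemic window is empty", call. = FALSE)
  if (any(endemic_window < 1) || any(endemic_window > ncol(counts)))
    stop("endemic window indexes periods outside the count matrix", call. = FALSE)
  if (length(pop) != nrow(counts) || any(pop <= 0))
    stop("'pop' must be positive, one per region", call. = FALSE)
  if (sum(pop) <= 0) stop("total population must be positive", call. = FALSE)
  rate <- sum(counts[, endemic_window, drop = FALSE]) / length(endemic_window)
  pop * rate / sum(pop)
}
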