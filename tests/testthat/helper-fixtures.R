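# Shared fixtures, memoised so expensive MCMC fits run once per test session
# no matter which test file asks first.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build()), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The recovery experiment: 4x4 rook lattice, 5 periods, expected counts in
# [50, 500], generative variances (1, 0.2, 0.2, 0.2), t errors with df = e_i.
recovery_study <- function() {
  fixture("recovery_study", function() {
    g <- lattice_graph(4, 4)
    ei <- with_seed_test(42, exp(runif(16, log(50), log(500))))
    cfg <- sim_config(g, n_times = 5, expected_counts = ei,
                      n_replicates = 1, seed = 1)
    list(graph = g, study = simulate_counts(cfg))
  })
}

# Quantile-model fit of the recovery replicate at tau = 0.5: 2 chains x
# 4000 retained draws (thinned from a longer run so the weakly identified
# interaction scale mixes).
recovery_fit <- function() {
  fixture("recovery_fit", function() {
    rs <- recovery_study()
    panel <- rs$study$replicates[[1]]$panel
    suppressWarnings(
      fit_quantile_model(panel, rs$graph,
                         model_config(tau = 0.5, chains = 2,
                                      iterations = 24000, burn_in = 8000,
                                      thin = 4, seed = 11)))
  })
}

# Null panel: relative risk identically 1, so y ~ Poisson(e).
null_panel <- function() {
  fixture("null_panel", function() {
    g <- lattice_graph(4, 4)
    ei <- with_seed_test(7, exp(runif(16, log(50), log(500))))
    y <- with_seed_test(8, matrix(rpois(80, rep(ei, 5)), 16, 5))
    list(graph = g,
         panel = panel_data(y, ei, region_ids = g$region_ids))
  })
}

# run expr under a local seed without disturbing the session RNG
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# small config for smoke-level fits where only correctness, not
# convergence, is under test
smoke_config <- function(...) {
  model_config(chains = 2, iterations = 600, burn_in = 300, ...)
}
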