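# Shared helpers: fast sampler settings for tests and the packaged fixture.

fast_mcmc <- function(seed = 1, n_kept = 2000) {
  mcmc_settings(n_chains = 1, n_burnin = 1000, n_kept_per_chain = n_kept,
                thinning = 2, seed = seed, n_adapt = 500)
}

fixture_table <- function() {
  read_species_table(extrisk_example("swio_endemics.csv"))
}

quiet_fit <- function(...) suppressWarnings(fit_trend(...))

# Minimal hand-built fit object for closed-form checks that need full
# control of the posterior draws.
fake_fit <- function(years, mu_draws, rbar_draws = NULL) {
  n <- nrow(mu_draws)
  structure(
    list(years = years, mu_draws = mu_draws,
         rbar_draws = rbar_draws %||% rep(0, n),
         sigma2_draws = rep(0.01, n),
         logq_draws = matrix(0, n, 1), obs_var_draws = matrix(0.01, n, 1),
         index_ids = "index_01", chain_id = rep(1L, n),
         data = tibble::tibble(index_id = "index_01",
                               survey_type = "trawl",
                               year = years,
                               value = exp(apply(mu_draws, 2, stats::median))),
         settings = mcmc_settings(seed = 1), geweke = NULL,
         converged = TRUE),
    class = "trend_fit"
  )
}

`%||%` <- rlang::`%||%`

# Brute-force HPD oracle: enumerate every pair of sorted draws and keep
# the narrowest closed interval spanning at least gap + 1 draws, where
# gap = ceiling(mass * n) inter-draw steps.
hpd_brute_force <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  gap <- max(1L, min(n - 1L, as.integer(ceiling(mass * n))))
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && sum(x >= x[i] & x <= x[j]) >= gap + 1 &&
          (x[j] - x[i]) < (best[2] - best[1])) {
        best <- c(x[i], x[j])
      }
    }
  }
  best
}

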