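test_that("noiseless exponential data recover the log-linear slope", {
  sim <- sim_abundance_indices(seed = 1, n_years = 20, start_year = 2000,
                               rbar = 0.1, sigma2 = 0, obs_sd = 0)
  fit <- quiet_fit(sim$data, fast_mcmc(seed = 1))
  expect_lt(abs(median(fit$rbar_draws) - 0.1), 0.01)
})

test_that("a constant index yields an HPD for rbar containing zero", {
  flat <- tibble::tibble(index_id = "index_01", survey_type = "trawl",
                         year = 2000:2014, value = 5)
  fit <- quiet_fit(flat, fast_mcmc(seed = 2))
  hpd <- hpd_interval(fit$rbar_draws)
  expect_lte(hpd[1], 0)
  expect_gte(hpd[2], 0)
  expect_lte(hpd[1], median(fit$rbar_draws))
  expect_gte(hpd[2], median(fit$rbar_draws))
})

test_that("fits are bit-identical for identical seeds and settings", {
  sim <- sim_abundance_indices(seed = 9, n_years = 12)
  f1 <- quiet_fit(sim$data, fast_mcmc(seed = 3, n_kept = 500))
  f2 <- quiet_fit(sim$data, fast_mcmc(seed = 3, n_kept = 500))
  expect_identical(f1$rbar_draws, f2$rbar_draws)
  expect_identical(f1$mu_draws, f2$mu_draws)
})

test_that("an index rescaled by a constant gives the same trend", {
  sim <- sim_abundance_indices(seed = 4, n_years = 15, rbar = -0.04,
                               sigma2 = 0.005, obs_sd = 0.2)
  fit1 <- quiet_fit(sim$data, fast_mcmc(seed = 5))
  scaled <- dplyr::mutate(sim$data, value = value * 37.5)
  fit2 <- quiet_fit(scaled, fast_mcmc(seed = 5))
  c1 <- change_over_window(fit1, 1991, 2005)
  c2 <- change_over_window(fit2, 1991, 2005)
  # same seeds, same relative data: the sampled trajectories differ only
  # through the initial-state prior centring, so changes agree closely
  expect_equal(median(c1), median(c2), tolerance = 0.02)
})

test_that("two scalar-multiple indices match the single-index posterior", {
  sim <- sim_abundance_indices(seed = 6, n_years = 27, rbar = -0.04,
                               sigma2 = 0.005, obs_sd = 0.2)
  st <- mcmc_settings(n_chains = 1, n_burnin = 3000,
                      n_kept_per_chain = 8000, thinning = 3, seed = 7,
                      n_adapt = 500)
  single <- quiet_fit(sim$data, st)
  doubled <- dplyr::bind_rows(
    sim$data,
    dplyr::mutate(sim$data, index_id = "index_02", value = value * 3)
  )
  both <- quiet_fit(doubled, st)
  expect_lt(abs(median(single$rbar_draws) - median(both$rbar_draws)), 0.005)
})

test_that("latent states bridge unobserved years inside the span", {
  sim <- sim_abundance_indices(seed = 8, n_years = 15, obs_sd = 0.1)
  gappy <- dplyr::filter(sim$data, !year %in% c(1995, 1996))
  fit <- quiet_fit(gappy, fast_mcmc(seed = 8))
  expect_equal(fit$years, 1991:2005)
  expect_false(anyNA(fit$mu_draws))
})

test_that("validation rejects unusable index data", {
  bad <- tibble::tibble(index_id = "a", year = 1:4, value = c(1, 2, -1, 3))
  expect_error(fit_trend(bad), class = "extrisk_validation_error")
  short <- tibble::tibble(index_id = "a", year = 1:2, value = c(1, 2))
  expect_error(fit_trend(short), class = "extrisk_validation_error")
})

test_that("tidy, glance and autoplot expose the fitted trajectory", {
  sim <- sim_abundance_indices(seed = 10, n_years = 10)
  fit <- quiet_fit(sim$data, fast_mcmc(seed = 10, n_kept = 500))
  td <- tidy(fit)
  expect_equal(td$year, fit$years)
  expect_true(all(td$mu_lower <= td$mu_median & td$mu_median <= td$mu_upper))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 500)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("percent change over a window follows the draws exactly", {
  years <- 2000:2010
  n <- 200
  # deterministic trajectory halving over the span
  mu <- matrix(rep(seq(log(2), log(1), length.out = 11), each = n), n)
  fit <- fake_fit(years, mu)
  ch <- change_over_window(fit, 2000, 2010)
  expect_equal(unique(ch), -50)
  smry <- summarize_change(ch)
  expect_equal(smry$median_change, -50)
  expect_equal(smry$hpd_lower, smry$hpd_upper)

  flat <- fake_fit(years, matrix(1.7, n, 11))
  expect_equal(unique(change_over_window(flat, 2000, 2010)), 0)

  # matches direct recomputation from stored draws
  ragged <- fake_fit(years, matrix(rnorm(n * 11), n))
  expect_equal(change_over_window(ragged, 2003, 2008),
               100 * (exp(ragged$mu_draws[, 9] - ragged$mu_draws[, 4]) - 1))

  expect_error(change_over_window(flat, 1990, 2010),
               class = "extrisk_window_error")
  expect_error(change_over_window(flat, 2010, 2000),
               class = "extrisk_window_error")
})

test_that("3GL change uses the window when it fits and rbar beyond it", {
  years <- 1991:2017  # 26-year span
  n <- 500
  mu <- matrix(rep(seq(0, log(0.5), length.out = 27), each = n), n)
  fit <- fake_fit(years, mu, rbar_draws = rep(log(0.61) / 27, n))

  # 3GL equal to the observed span: identical to the windowed change
  expect_equal(change_over_3gl(fit, 26),
               change_over_window(fit, 1991, 2017))

  # 3GL beyond the span: closed-form extrapolation from rbar
  ch60 <- change_over_3gl(fit, 60)
  expect_equal(unique(ch60), 100 * (exp(log(0.61) / 27 * 60) - 1))
  expect_lt(abs(median(ch60) - (-66.6)), 0.1)

  expect_error(change_over_3gl(fit, -3), class = "extrisk_validation_error")
})

test_that("posterior predictive checks pass on model-generated data", {
  flags <- vapply(1:20, function(s) {
    sim <- sim_abundance_indices(seed = 100 + s, n_years = 15,
                                 rbar = -0.03, sigma2 = 0.005,
                                 obs_sd = 0.25)
    fit <- quiet_fit(sim$data, fast_mcmc(seed = s, n_kept = 1000))
    attr(posterior_predictive_check(fit), "prop_flagged")
  }, numeric(1))
  expect_lte(mean(flags), 0.10)
})

test_that("posterior predictive checks flag a gross outlier", {
  sim <- sim_abundance_indices(seed = 21, n_years = 25, obs_sd = 0.1,
                               sigma2 = 0.002)
  data <- sim$data
  data$value[13] <- data$value[13] * 100
  fit <- quiet_fit(data, fast_mcmc(seed = 21))
  ppc <- posterior_predictive_check(fit)
  expect_true(ppc$flagged[13])
})

test_that("posterior predictive checks raise no flags on noise-free data", {
  sim <- sim_abundance_indices(seed = 22, n_years = 12, rbar = -0.05,
                               sigma2 = 0, obs_sd = 0)
  fit <- quiet_fit(sim$data, fast_mcmc(seed = 22))
  ppc <- posterior_predictive_check(fit)
  expect_equal(sum(ppc$flagged), 0)
})
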