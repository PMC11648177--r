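# Bayesian exponential state-space model for relative-abundance indices.
#
# State process:        mu[t+1] = mu[t] + r[t],  r[t] ~ N(rbar, sigma2)
# Observation process:  log I[i,t] = log q[i] + mu[t] + eps[i,t],
#                       eps[i,t] ~ N(0, tau2[i])
#
# mu[t] is log expected abundance in year t, rbar the mean annual log rate
# of change and sigma2 the process variance. Each survey index i has its
# own constant catchability offset log q[i] (the first index is fixed at
# q = 1 for identifiability) and its own observation variance tau2[i].
# Priors: rbar ~ N(0, 1000); sigma2 and each tau2 ~ inverse-gamma(0.001,
# 0.001); log q[i] ~ N(0, 1e6) for i > 1; the initial state is given a
# diffuse normal prior (sd 1000 on the log scale) centred on the log of
# the first observation. Inference is by Gibbs/Metropolis sampling in JAGS.

#' MCMC sampler settings
#'
#' Defaults follow the standard schedule for this model class: three
#' chains, 30,000 burn-in iterations, then 60,000 iterations per chain
#' thinned by 6 to keep 10,000 draws per chain — 30,000 posterior draws in
#' total.
#'
#' @param n_chains number of independent chains.
#' @param n_burnin iterations discarded from the start of each chain.
#' @param n_kept_per_chain posterior draws retained per chain.
#' @param thinning keep every `thinning`-th post-burn-in iteration.
#' @param seed integer seed; chain RNGs are derived from it, so identical
#'   settings give bit-identical posteriors.
#' @param n_adapt JAGS adaptation iterations before burn-in.
#' @return A list of settings with class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_burnin = 30000,
                          n_kept_per_chain = 10000, thinning = 6,
                          seed = 1, n_adapt = 1000) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_kept_per_chain >= 1,
            thinning >= 1, n_adapt >= 0)
  structure(
    list(n_chains = as.integer(n_chains), n_burnin = as.integer(n_burnin),
         n_kept_per_chain = as.integer(n_kept_per_chain),
         thinning = as.integer(thinning), seed = as.integer(seed),
         n_adapt = as.integer(n_adapt)),
    class = "mcmc_settings"
  )
}

#' Read abundance index time series
#'
#' @param path CSV with columns `index_id`, `survey_type`, `year`, `value`
#'   (one row per observation; `value` is a strictly positive relative
#'   abundance such as kg per area swept or fish per angler-day).
#' @return A validated tibble.
#' @export
read_abundance_indices <- function(path) {
  if (!file.exists(path)) {
    stop_extrisk(paste0("file not found: ", path), "extrisk_io_error")
  }
  idx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_indices(idx)
}

validate_indices <- function(indices) {
  needed <- c("index_id", "year", "value")
  missing <- setdiff(needed, names(indices))
  if (length(missing) > 0) {
    stop_extrisk(paste0("index data missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "extrisk_format_error")
  }
  if (!"survey_type" %in% names(indices)) indices$survey_type <- "other"
  if (nrow(indices) == 0) {
    stop_extrisk("index data has no observations", "extrisk_validation_error")
  }
  if (anyNA(indices$value) || any(indices$value <= 0)) {
    stop_extrisk("abundance values must be strictly positive (log is taken)",
                 "extrisk_validation_error")
  }
  counts <- dplyr::count(indices, .data$index_id)
  if (any(counts$n < 3)) {
    stop_extrisk(paste0("index '", counts$index_id[counts$n < 3][1],
                        "' has fewer than 3 observation years"),
                 "extrisk_validation_error")
  }
  dup <- dplyr::count(indices, .data$index_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_extrisk(paste0("duplicate year ", dup$year[1], " in index '",
                        dup$index_id[1], "'"),
                 "extrisk_validation_error")
  }
  as_tibble(indices) |> arrange(.data$index_id, .data$year)
}

jags_model_string <- function(n_indices) {
  obs_prior <- if (n_indices > 1) {
    "
  for (i in 2:I) { logq[i] ~ dnorm(0, 1.0E-6) }"
  } else {
    ""
  }
  paste0("
model {
  mu[1] ~ dnorm(mu0, 1.0E-6)
  for (t in 1:(T-1)) {
    r[t] ~ dnorm(rbar, prec_proc)
    mu[t+1] <- mu[t] + r[t]
  }
  rbar ~ dnorm(0, 0.001)
  prec_proc ~ dgamma(0.001, 0.001)
  sigma2 <- 1 / prec_proc
  logq[1] <- 0", obs_prior, "
  for (i in 1:I) {
    prec_obs[i] ~ dgamma(0.001, 0.001)
    tau2[i] <- 1 / prec_obs[i]
  }
  for (k in 1:Nobs) {
    logy[k] ~ dnorm(logq[idx[k]] + mu[tix[k]], prec_obs[idx[k]])
  }
}")
}

#' Fit the exponential state-space trend model
#'
#' Fits the latent log-abundance trajectory shared by one or more
#' relative-abundance indices. Years missing inside the observed span are
#' treated as latent states with no likelihood contribution, so gaps are
#' handled natively. After sampling, each monitored parameter chain is
#' screened with the Geweke stationarity diagnostic; a fit whose chains
#' fail the screen is returned flagged (`converged = FALSE`) with a
#' warning, not an error.
#'
#' @param indices tibble (or data frame) of observations with columns
#'   `index_id`, `year`, `value` and optionally `survey_type`.
#' @param settings an [mcmc_settings()] object.
#' @return An object of class `trend_fit`: posterior draw matrices for the
#'   latent states (`mu_draws`, draws x years), `rbar_draws`,
#'   `sigma2_draws`, per-index `logq_draws` and `obs_var_draws`, the
#'   Geweke report, and the data. Use [tidy()] for the annual trajectory,
#'   [glance()] for scalar summaries, and [autoplot()] to plot.
#' @examples
#' \donttest{
#' sim <- sim_abundance_indices(seed = 1, n_years = 15)
#' fit <- fit_trend(sim$data, mcmc_settings(n_chains = 1, n_burnin = 500,
#'                                          n_kept_per_chain = 500,
#'                                          thinning = 1, seed = 1))
#' glance(fit)
#' }
#' @export
fit_trend <- function(indices, settings = mcmc_settings()) {
  indices <- validate_indices(indices)
  index_ids <- unique(indices$index_id)
  n_idx <- length(index_ids)
  years <- seq(min(indices$year), max(indices$year))

  jags_data <- list(
    T = length(years),
    I = n_idx,
    Nobs = nrow(indices),
    logy = log(indices$value),
    idx = match(indices$index_id, index_ids),
    tix = match(indices$year, years),
    mu0 = log(indices$value[indices$index_id == index_ids[1]][1])
  )
  inits <- lapply(seq_len(settings$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = settings$seed * 1000L + ch)
  })

  model <- rjags::jags.model(
    textConnection(jags_model_string(n_idx)),
    data = jags_data, inits = inits, n.chains = settings$n_chains,
    n.adapt = settings$n_adapt, quiet = TRUE
  )
  if (settings$n_burnin > 0) {
    stats::update(model, settings$n_burnin, progress.bar = "none")
  }
  samples <- rjags::coda.samples(
    model, variable.names = c("mu", "rbar", "sigma2", "logq", "tau2"),
    n.iter = settings$n_kept_per_chain * settings$thinning,
    thin = settings$thinning, progress.bar = "none"
  )

  draws <- do.call(rbind, lapply(samples, as.matrix))
  chain_id <- rep(seq_len(settings$n_chains),
                  each = settings$n_kept_per_chain)
  mu_cols <- paste0("mu[", seq_along(years), "]")
  # JAGS drops the bracket on length-1 monitored nodes
  q_cols <- if (n_idx == 1) "logq" else paste0("logq[", seq_len(n_idx), "]")
  tau_cols <- if (n_idx == 1) "tau2" else paste0("tau2[", seq_len(n_idx), "]")

  geweke <- geweke_report(draws, chain_id,
                          params = c("rbar", "sigma2"))
  converged <- all(geweke$p >= 0.05)
  if (!converged) {
    warn(paste0("Geweke diagnostic failed (min p = ",
                signif(min(geweke$p), 3),
                "); fit flagged as not converged"),
         class = "extrisk_convergence_warning")
  }

  structure(
    list(
      years = years,
      mu_draws = draws[, mu_cols, drop = FALSE],
      rbar_draws = as.numeric(draws[, "rbar"]),
      sigma2_draws = as.numeric(draws[, "sigma2"]),
      logq_draws = draws[, q_cols, drop = FALSE],
      obs_var_draws = draws[, tau_cols, drop = FALSE],
      index_ids = index_ids,
      chain_id = chain_id,
      data = indices,
      settings = settings,
      geweke = geweke,
      converged = converged
    ),
    class = "trend_fit"
  )
}

geweke_report <- function(draws, chain_id, params) {
  purrr::map_dfr(params, function(par) {
    purrr::map_dfr(unique(chain_id), function(ch) {
      x <- draws[chain_id == ch, par]
      gz <- tryCatch(geweke_z(x), error = function(e) {
        tibble(z = NA_real_, p = 0)
      })
      tibble(parameter = par, chain = ch, z = gz$z, p = gz$p)
    })
  })
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Exponential state-space trend fit\n")
  cat("  years:", min(x$years), "-", max(x$years),
      " indices:", paste(x$index_ids, collapse = ", "), "\n")
  cat("  posterior draws:", length(x$rbar_draws),
      sprintf("(%d chains)", x$settings$n_chains), "\n")
  hpd <- hpd_interval(x$rbar_draws)
  cat(sprintf("  rbar: median %.4f, 95%% HPD [%.4f, %.4f]\n",
              median(x$rbar_draws), hpd[1], hpd[2]))
  cat("  converged (Geweke p >= 0.05):", x$converged, "\n")
  invisible(x)
}

#' Tidy the fitted trajectory of a trend fit
#'
#' @param x a `trend_fit`.
#' @param mass posterior mass of the HPD interval.
#' @param ... unused.
#' @return A tibble with one row per fitted year: posterior median and HPD
#'   bounds of the latent log abundance (`mu_*`) and of relative abundance
#'   (`abundance_*`, the exponential of the latent state).
#' @export
tidy.trend_fit <- function(x, mass = 0.95, ...) {
  purrr::map_dfr(seq_along(x$years), function(j) {
    mu <- x$mu_draws[, j]
    hpd <- hpd_interval(mu, mass)
    tibble(
      year = x$years[j],
      mu_median = median(mu), mu_lower = hpd[1], mu_upper = hpd[2],
      abundance_median = exp(median(mu)),
      abundance_lower = exp(hpd[1]), abundance_upper = exp(hpd[2])
    )
  })
}

#' One-row summary of a trend fit
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return A one-row tibble: posterior median and 95% HPD of the mean
#'   annual log rate `rbar`, posterior median process variance, draw
#'   count, and the Geweke convergence flag.
#' @export
glance.trend_fit <- function(x, ...) {
  hpd <- hpd_interval(x$rbar_draws)
  tibble(
    rbar_median = median(x$rbar_draws),
    rbar_lower = hpd[1], rbar_upper = hpd[2],
    sigma2_median = median(x$sigma2_draws),
    n_draws = length(x$rbar_draws),
    n_chains = x$settings$n_chains,
    converged = x$converged
  )
}

#' Plot a fitted abundance trajectory
#'
#' Posterior median and HPD ribbon of relative abundance, with the
#' observed index values (rescaled by the posterior median catchability
#' of their index) overlaid as points.
#'
#' @param object a `trend_fit`.
#' @param mass posterior mass of the ribbon.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.trend_fit <- function(object, mass = 0.95, ...) {
  traj <- tidy(object, mass = mass)
  q_med <- exp(apply(object$logq_draws, 2, median))
  obs <- object$data |>
    mutate(scaled = .data$value / q_med[match(.data$index_id,
                                              object$index_ids)])
  ggplot(traj, aes(x = .data$year)) +
    geom_ribbon(aes(ymin = .data$abundance_lower,
                    ymax = .data$abundance_upper), alpha = 0.25) +
    geom_line(aes(y = .data$abundance_median)) +
    geom_point(data = obs, aes(y = .data$scaled,
                               shape = .data$index_id)) +
    labs(x = "Year", y = "Relative abundance", shape = "Index") +
    theme_minimal()
}
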