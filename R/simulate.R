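# Seeded simulators mirroring the generative structure the analysis
# assumes: a latent exponential trend with year-to-year process
# variability observed through index-specific catchability and log-normal
# noise; multinomial species tables; Dirichlet range matrices.
#
# Defaults emulate the survey layout behind the regional assessment: 27
# annual trawl observations (1991-2017) and a log-scale observation noise
# sd of 0.3 (the surveys themselves publish no noise magnitude; 0.3 is a
# realistic CPUE figure, stated as the package default, and configurable).

#' Simulate relative-abundance index time series
#'
#' Forward simulation of the state-space trend model:
#' `mu[1] = log(initial_abundance)`, `mu[t+1] = mu[t] + r[t]` with
#' `r[t] ~ N(rbar, sigma2)`, and observations
#' `I[i, t] = q[i] * exp(mu[t] + eps)`, `eps ~ N(0, obs_sd^2)`.
#' Identical seed and parameters give bit-identical output.
#'
#' @param seed integer seed.
#' @param n_years number of consecutive annual observations (>= 3).
#' @param start_year first survey year.
#' @param rbar mean annual log rate of change.
#' @param sigma2 process variance of the annual rates (>= 0).
#' @param obs_sd log-scale observation noise standard deviation (>= 0).
#' @param n_indices number of indices observing the same trajectory.
#' @param q per-index catchability scalars (recycled to `n_indices`).
#' @param initial_abundance abundance at the first year (> 0).
#' @param survey_type survey label(s) for the generated indices.
#' @return A list: `data`, a tibble of observations (`index_id`,
#'   `survey_type`, `year`, `value`) suitable for [fit_trend()]; `truth`,
#'   a tibble of the latent trajectory (`year`, `mu`); and `params`, the
#'   generating parameters.
#' @examples
#' sim <- sim_abundance_indices(seed = 42, rbar = -0.05)
#' head(sim$data)
#' @export
sim_abundance_indices <- function(seed, n_years = 27, start_year = 1991,
                                  rbar = -0.05, sigma2 = 0.01,
                                  obs_sd = 0.3, n_indices = 1, q = 1,
                                  initial_abundance = 1,
                                  survey_type = "trawl") {
  if (n_years < 3) {
    stop_extrisk("n_years must be at least 3", "extrisk_validation_error")
  }
  if (sigma2 < 0 || obs_sd < 0 || initial_abundance <= 0 || n_indices < 1) {
    stop_extrisk("invalid simulation config", "extrisk_validation_error")
  }
  q <- rep_len(q, n_indices)
  survey_type <- rep_len(survey_type, n_indices)
  years <- seq(start_year, length.out = n_years)
  with_seed(seed, {
    r <- rnorm(n_years - 1, rbar, sqrt(sigma2))
    mu <- cumsum(c(log(initial_abundance), r))
    data <- purrr::map_dfr(seq_len(n_indices), function(i) {
      tibble(
        index_id = sprintf("index_%02d", i),
        survey_type = survey_type[i],
        year = years,
        value = q[i] * exp(mu + rnorm(n_years, 0, obs_sd))
      )
    })
    list(
      data = data,
      truth = tibble(year = years, mu = mu),
      params = list(seed = seed, rbar = rbar, sigma2 = sigma2,
                    obs_sd = obs_sd, q = q,
                    initial_abundance = initial_abundance)
    )
  })
}

#' Simulate a species assessment table
#'
#' Draws each species' category at each epoch independently from the
#' supplied category frequencies (a multinomial per epoch).
#'
#' @param seed integer seed.
#' @param n_species number of species (> 0).
#' @param frequencies named list mapping epoch to a named numeric vector
#'   of category frequencies summing to 1, e.g.
#'   `list("2020" = c(LC = 0.5, VU = 0.5))`.
#' @return A species table tibble with `cat_<epoch>` columns.
#' @export
sim_species_table <- function(seed, n_species,
                              frequencies = list(
                                "2020" = c(CR = 1, EN = 5, VU = 7, NT = 7,
                                           LC = 33, DD = 17) / 70
                              )) {
  if (n_species < 1) {
    stop_extrisk("n_species must be positive", "extrisk_validation_error")
  }
  for (ep in names(frequencies)) {
    f <- frequencies[[ep]]
    if (is.null(names(f)) || !all(names(f) %in% red_list_categories) ||
        abs(sum(f) - 1) > 1e-9 || any(f < 0)) {
      stop_extrisk(paste0("invalid category frequencies for epoch ", ep),
                   "extrisk_validation_error")
    }
  }
  with_seed(seed, {
    tbl <- tibble(
      latin_binomial = sprintf("Simulatus species%03d", seq_len(n_species)),
      common_name = sprintf("Simulated species %03d", seq_len(n_species)),
      order = "Simuliformes", family = "Simulidae"
    )
    for (ep in names(frequencies)) {
      f <- frequencies[[ep]]
      tbl[[cat_column(ep)]] <- sample(names(f), n_species, replace = TRUE,
                                      prob = f)
    }
    tbl$threat_codes <- NA_character_
    tbl
  })
}

#' Simulate a range-proportion matrix
#'
#' Per species, range proportions across countries are drawn from a
#' symmetric Dirichlet distribution, so each row sums to 1 (regional
#' endemics). Larger `concentration` pulls proportions toward
#' `1 / n_countries`.
#'
#' @param seed integer seed.
#' @param species character vector of species names.
#' @param countries character vector of country names (>= 1).
#' @param concentration positive Dirichlet concentration parameter.
#' @return A range-matrix tibble (see [read_range_matrix()]).
#' @export
sim_range_matrix <- function(seed, species, countries, concentration = 1) {
  if (length(countries) < 1 || length(species) < 1 || concentration <= 0) {
    stop_extrisk("invalid range-matrix config", "extrisk_validation_error")
  }
  with_seed(seed, {
    mat <- matrix(rgamma(length(species) * length(countries),
                         shape = concentration, rate = 1),
                  nrow = length(species))
    mat <- mat / rowSums(mat)
    out <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
    names(out) <- countries
    bind_cols(tibble(latin_binomial = species), out)
  })
}

#' Simulate a life-history table
#'
#' Draws maximum ages uniformly and maturity as a fraction of maximum
#' age, in ranges typical of coastal sharks and rays.
#'
#' @param seed integer seed.
#' @param species character vector of species names.
#' @param max_age_range range of maximum ages (years).
#' @param z adult-mortality factor.
#' @return A tibble with `latin_binomial`, `max_age`, `age_at_maturity`,
#'   `z` and the implied `gl`.
#' @export
sim_life_histories <- function(seed, species, max_age_range = c(8, 30),
                               z = 0.5) {
  with_seed(seed, {
    max_age <- round(stats::runif(length(species), max_age_range[1],
                                  max_age_range[2]), 1)
    maturity <- round(max_age * stats::runif(length(species), 0.3, 0.7), 1)
    tibble(latin_binomial = species, max_age = max_age,
           age_at_maturity = maturity, z = z,
           gl = generation_length(max_age, maturity, z))
  })
}
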