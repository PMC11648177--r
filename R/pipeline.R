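# Pipeline entry points tying the modules together: each reads the CSV
# formats the package defines, runs one analysis stage, and writes CSV/
# JSON outputs into an output directory. Every stage is deterministic
# given its inputs and seed; diagnostics records include the seed and
# package version.

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Fit the trend model from an index CSV and write summaries
#'
#' Reads an abundance-index CSV, fits [fit_trend()], and writes
#' `trajectory.csv` (per-year posterior median and 95% HPD of the latent
#' trajectory), `diagnostics.json` (Geweke report, convergence flag, draw
#' counts, seed, package version), and — when `three_gl_years` is given —
#' `change_3gl.csv` with the decline summary.
#'
#' @param index_csv path to an index CSV (see
#'   [read_abundance_indices()]).
#' @param out_dir output directory (created if absent).
#' @param settings an [mcmc_settings()] object.
#' @param three_gl_years optional assessment window in years.
#' @return Invisibly, a list with the `trend_fit` object and the written
#'   paths.
#' @export
run_fit_trend <- function(index_csv, out_dir,
                          settings = mcmc_settings(),
                          three_gl_years = NULL) {
  indices <- read_abundance_indices(index_csv)
  fit <- fit_trend(indices, settings)
  ensure_out_dir(out_dir)

  traj_path <- file.path(out_dir, "trajectory.csv")
  readr::write_csv(tidy(fit), traj_path, progress = FALSE)

  diag_path <- file.path(out_dir, "diagnostics.json")
  diagnostics <- list(
    package = "extrisk",
    version = as.character(utils::packageVersion("extrisk")),
    seed = settings$seed,
    n_chains = settings$n_chains,
    n_burnin = settings$n_burnin,
    n_draws = length(fit$rbar_draws),
    thinning = settings$thinning,
    converged = fit$converged,
    geweke = fit$geweke
  )
  jsonlite::write_json(diagnostics, diag_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths <- list(trajectory = traj_path, diagnostics = diag_path)
  if (!is.null(three_gl_years)) {
    change_path <- file.path(out_dir, "change_3gl.csv")
    draws <- change_over_3gl(fit, three_gl_years)
    readr::write_csv(
      bind_cols(tibble(three_gl_years = three_gl_years),
                summarize_change(draws)),
      change_path, progress = FALSE
    )
    paths$change_3gl <- change_path
  }
  invisible(list(fit = fit, paths = paths))
}

#' Assess declines for a set of fitted species and write the table
#'
#' Combines per-species trend fits with a life-history table to produce
#' one Criterion A2 assessment row per species. Expert overrides are
#' recorded next to the modeled category, never in place of it.
#'
#' @param fits named list of `trend_fit` objects, keyed by
#'   `latin_binomial`.
#' @param life_history_csv path to a life-history CSV (see
#'   [read_life_history()]); must cover every fitted species.
#' @param out_csv output CSV path.
#' @param overrides optional named character vector of expert category
#'   overrides keyed by `latin_binomial`.
#' @param nt_band passed to [assign_category()].
#' @return The assessment tibble (one row per species), invisibly; also
#'   written to `out_csv`.
#' @export
run_assess <- function(fits, life_history_csv, out_csv, overrides = NULL,
                       nt_band = c(20, 30)) {
  if (length(fits) == 0 || is.null(names(fits))) {
    stop_extrisk("fits must be a named list of trend_fit objects",
                 "extrisk_validation_error")
  }
  lh <- read_life_history(life_history_csv)
  unmatched <- setdiff(names(fits), lh$latin_binomial)
  if (length(unmatched) > 0) {
    stop_extrisk(paste0("no life history for: ",
                        paste(unmatched, collapse = ", ")),
                 "extrisk_validation_error")
  }
  rows <- purrr::map_dfr(names(fits), function(sp) {
    gl <- lh$gl[lh$latin_binomial == sp]
    window <- three_gl(gl)
    fit <- fits[[sp]]
    draws <- change_over_3gl(fit, window)
    observed <- summarize_change(
      change_over_window(fit, min(fit$years), max(fit$years))
    )$median_change
    bind_cols(
      tibble(latin_binomial = sp, gl = gl,
             observed_change = observed),
      assess_decline(draws, window, nt_band = nt_band,
                     override = if (sp %in% names(overrides)) {
                       unname(overrides[[sp]])
                     })
    )
  })
  readr::write_csv(rows, out_csv, progress = FALSE)
  invisible(rows)
}

#' Compute RLI (and responsibility) reports from CSV inputs
#'
#' Reads a species table and optionally a range matrix, and writes
#' `rli.csv` (the per-epoch RLI series, with values also given at the
#' conventional 3-decimal reporting precision) plus, when a range matrix
#' is supplied, `ncr.csv` with raw and normalized national conservation
#' responsibility scores at the latest epoch.
#'
#' @param species_csv path to a species table CSV.
#' @param epochs integer vector of assessment epochs.
#' @param out_dir output directory.
#' @param ranges_csv optional path to a range-matrix CSV.
#' @return Invisibly, a list with the RLI series, the responsibility
#'   table (or `NULL`), and the written paths.
#' @export
run_rli <- function(species_csv, epochs = c(1980, 2005, 2020), out_dir,
                    ranges_csv = NULL) {
  table <- read_species_table(species_csv, epochs)
  ranges <- if (!is.null(ranges_csv)) read_range_matrix(ranges_csv)
  series <- rli_series(table, epochs, ranges = ranges) |>
    mutate(rli_reported = round_half_up(.data$rli, 3))
  ensure_out_dir(out_dir)
  rli_path <- file.path(out_dir, "rli.csv")
  readr::write_csv(series, rli_path, progress = FALSE)
  paths <- list(rli = rli_path)

  ncr <- NULL
  if (!is.null(ranges)) {
    ncr <- national_responsibility(table, max(epochs), ranges) |>
      mutate(score_reported = round_half_up(.data$score, 3))
    ncr_path <- file.path(out_dir, "ncr.csv")
    readr::write_csv(ncr, ncr_path, progress = FALSE)
    paths$ncr <- ncr_path
  }
  invisible(list(rli = series, ncr = ncr, paths = paths))
}
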