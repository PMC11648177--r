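# Red List Index (global and country-disaggregated) and national
# conservation responsibility scores.

#' Red List category threat weights
#'
#' Weights used by the Red List Index: LC 0, NT 1, VU 2, EN 3, CR 4, with
#' Extinct and Extinct in the Wild at the maximum threat score
#' `w_ex = 5`. Data Deficient species carry no weight — they are excluded
#' from RLI and responsibility computations entirely.
#'
#' @param w_ex maximum threat score, assigned to EX/EW.
#' @return A list with `weights` (named numeric over the category codes)
#'   and `w_ex`.
#' @export
threat_weights <- function(w_ex = 5) {
  weights <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = w_ex,
               EX = w_ex)
  stopifnot(all(diff(weights[c("LC", "NT", "VU", "EN", "CR")]) > 0),
            w_ex > weights[["CR"]])
  list(weights = weights, w_ex = w_ex)
}

rli_weights_for <- function(table, epoch, weights) {
  col <- assert_epoch(table, epoch)
  cats <- table[[col]]
  keep <- cats != "DD"
  list(keep = keep, w = unname(weights$weights[cats[keep]]))
}

#' Global (equal-weight) Red List Index
#'
#' `RLI = 1 - sum(W_s) / (w_ex * N)` over the `N` assessed (non-DD)
#' species, where `W_s` is the threat weight of species `s` at the epoch.
#' An RLI of 1 means every assessed species is Least Concern; 0 means all
#' are Extinct.
#'
#' @param table a species table.
#' @param epoch an assessment epoch present in the table.
#' @param weights a [threat_weights()] object.
#' @return The RLI value in `[0, 1]` (unrounded; reports conventionally
#'   print 3 decimals).
#' @examples
#' tbl <- read_species_table(extrisk_example("swio_endemics.csv"))
#' round(global_rli(tbl, 2020), 3)
#' @export
global_rli <- function(table, epoch, weights = threat_weights()) {
  parts <- rli_weights_for(table, epoch, weights)
  n <- sum(parts$keep)
  if (n == 0) {
    stop_extrisk("RLI undefined: no assessed (non-DD) species",
                 "extrisk_undefined_error")
  }
  1 - sum(parts$w) / (weights$w_ex * n)
}

#' Country-disaggregated Red List Index
#'
#' Range-weighted RLI for one country:
#' `RLI(t, u) = 1 - sum_s(W_s * p_su) / (w_ex * sum_s(p_su))`, where
#' `p_su` is the proportion of species `s`'s global range inside country
#' `u`'s EEZ. Sums run over assessed (non-DD) species. With a single
#' country holding every species' entire range this reduces to the global
#' RLI.
#'
#' @inheritParams global_rli
#' @param ranges a range-proportion matrix covering the table's assessed
#'   species (see [read_range_matrix()]).
#' @param country a country column name of `ranges`.
#' @return The country RLI value in `[0, 1]`.
#' @export
country_rli <- function(table, epoch, ranges, country,
                        weights = threat_weights()) {
  if (!country %in% names(ranges)) {
    stop_extrisk(paste0("country '", country, "' not in range matrix"),
                 "extrisk_lookup_error")
  }
  parts <- rli_weights_for(table, epoch, weights)
  sp <- table$latin_binomial[parts$keep]
  p <- ranges[[country]][match(sp, ranges$latin_binomial)]
  if (anyNA(p)) {
    stop_extrisk(paste0("range matrix missing species: ",
                        paste(head(sp[is.na(p)], 3), collapse = ", ")),
                 "extrisk_validation_error")
  }
  if (sum(p) <= 0) {
    stop_extrisk(paste0("no assessed species has range in '", country, "'"),
                 "extrisk_undefined_error")
  }
  1 - sum(parts$w * p) / (weights$w_ex * sum(p))
}

#' National conservation responsibility scores
#'
#' For each country, the sum over assessed (non-DD) species of the
#' species' threat weight times the proportion of its range in the
#' country's EEZ. With `normalize = TRUE` scores are divided by the
#' maximum so the top country scores 1.
#'
#' @inheritParams country_rli
#' @param normalize divide by the maximum raw score (default `TRUE`).
#' @return A tibble with columns `country`, `score_raw`, and `score`
#'   (normalized or equal to `score_raw`), sorted by descending score.
#' @export
national_responsibility <- function(table, epoch, ranges,
                                    weights = threat_weights(),
                                    normalize = TRUE) {
  parts <- rli_weights_for(table, epoch, weights)
  sp <- table$latin_binomial[parts$keep]
  long <- range_matrix_long(ranges) |>
    filter(.data$latin_binomial %in% sp)
  missing <- setdiff(sp, ranges$latin_binomial)
  if (length(missing) > 0) {
    stop_extrisk(paste0("range matrix missing species: ",
                        paste(head(missing, 3), collapse = ", ")),
                 "extrisk_validation_error")
  }
  w_by_sp <- setNames(parts$w, sp)
  scores <- long |>
    mutate(wp = w_by_sp[.data$latin_binomial] * .data$p) |>
    group_by(.data$country) |>
    summarise(score_raw = sum(.data$wp), .groups = "drop")
  if (normalize) {
    top <- max(scores$score_raw)
    if (top == 0) {
      warn("all raw responsibility scores are zero; returning raw zeros",
           class = "extrisk_normalization_warning")
      scores$score <- scores$score_raw
    } else {
      scores$score <- scores$score_raw / top
    }
  } else {
    scores$score <- scores$score_raw
  }
  arrange(scores, desc(.data$score), .data$country)
}

#' Red List Index series across epochs
#'
#' Computes the RLI at each epoch — globally, and per country when a range
#' matrix is supplied — holding the species set constant across epochs.
#'
#' @inheritParams global_rli
#' @param epochs integer vector of epochs present in the table.
#' @param ranges optional range-proportion matrix; when given, a series is
#'   added for each of its countries (or the subset named in
#'   `countries`).
#' @param countries optional character vector restricting the country
#'   series.
#' @return A tibble with columns `scope` (`"global"` or a country name),
#'   `epoch`, `rli`, and `n_assessed` (non-DD species counted in the
#'   scope).
#' @examples
#' tbl <- read_species_table(extrisk_example("swio_endemics.csv"))
#' rli_series(tbl, c(1980, 2005, 2020))
#' @export
rli_series <- function(table, epochs, ranges = NULL, countries = NULL,
                       weights = threat_weights()) {
  n_assessed_global <- purrr::map_int(epochs, function(ep) {
    sum(table[[assert_epoch(table, ep)]] != "DD")
  })
  out <- tibble(
    scope = "global",
    epoch = as.integer(epochs),
    rli = purrr::map_dbl(epochs, ~ global_rli(table, .x, weights)),
    n_assessed = n_assessed_global
  )
  if (!is.null(ranges)) {
    countries <- countries %||% setdiff(names(ranges), "latin_binomial")
    country_rows <- purrr::map_dfr(countries, function(cn) {
      purrr::map_dfr(epochs, function(ep) {
        keep <- table[[cat_column(ep)]] != "DD"
        sp <- table$latin_binomial[keep]
        p <- ranges[[cn]][match(sp, ranges$latin_binomial)]
        tibble(
          scope = cn, epoch = as.integer(ep),
          rli = country_rli(table, ep, ranges, cn, weights),
          n_assessed = sum(p > 0, na.rm = TRUE)
        )
      })
    })
    out <- bind_rows(out, country_rows)
  }
  out
}

#' Plot a Red List Index series
#'
#' @param series output of [rli_series()].
#' @return A ggplot object: RLI against epoch, one line per scope.
#' @export
plot_rli <- function(series) {
  ggplot(series, aes(x = .data$epoch, y = .data$rli,
                     colour = .data$scope)) +
    geom_line() +
    geom_point() +
    labs(x = "Assessment year", y = "Red List Index", colour = NULL) +
    theme_minimal()
}
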