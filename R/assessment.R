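# Generation-length arithmetic and mapping of decline posteriors to IUCN
# Criterion A2 categories.

#' Generation length from longevity and maturity
#'
#' `GL = max_age + (max_age - age_at_maturity) * z`, where `z` reflects
#' adult survivorship; the default `z = 0.5` allows for truncation of the
#' age structure by exploitation and for underestimated ages in sharks and
#' rays. GL is linear in `z` and equals `max_age` at `z = 0`.
#'
#' @param max_age maximum age in years.
#' @param age_at_maturity female age at maturity in years
#'   (`0 < age_at_maturity <= max_age`).
#' @param z dimensionless adult-mortality factor in `[0, 1]`.
#' @return Generation length in years (vectorized).
#' @examples
#' generation_length(20, 10)      # 25
#' generation_length(15, 5, 0.3)  # 18
#' @export
generation_length <- function(max_age, age_at_maturity, z = 0.5) {
  if (any(!is.finite(max_age)) || any(!is.finite(age_at_maturity)) ||
      any(age_at_maturity <= 0) || any(age_at_maturity > max_age)) {
    stop_extrisk("need 0 < age_at_maturity <= max_age",
                 "extrisk_validation_error")
  }
  if (any(z < 0) || any(z > 1)) {
    stop_extrisk("z must lie in [0, 1]", "extrisk_validation_error")
  }
  max_age + (max_age - age_at_maturity) * z
}

#' Three generation lengths
#'
#' The time window over which Criterion A population reduction is
#' measured.
#'
#' @param gl generation length in years (> 0).
#' @return `3 * gl`, in years.
#' @examples
#' three_gl(20)  # 60
#' @export
three_gl <- function(gl) {
  if (any(!is.finite(gl)) || any(gl <= 0)) {
    stop_extrisk("generation length must be positive",
                 "extrisk_validation_error")
  }
  3 * gl
}

#' Criterion A2 category probabilities from a decline posterior
#'
#' Converts posterior draws of percent population change over three
#' generation lengths into probabilities of the Criterion A2 categories,
#' using the IUCN decline thresholds: Critically Endangered >= 80%
#' decline, Endangered 50-80%, Vulnerable 30-50%, and below 30% neither
#' (`LC_or_NT`). Probabilities are empirical fractions of draws and
#' partition the draw set exactly.
#'
#' @param change_draws numeric vector of percent-change draws (negative =
#'   decline).
#' @param thresholds named numeric vector of decline thresholds, in
#'   percent decline: `c(CR = 80, EN = 50, VU = 30)`.
#' @return A tibble with columns `category` (`CR`, `EN`, `VU`,
#'   `LC_or_NT`) and `probability` (summing to 1).
#' @examples
#' criterion_a2_probabilities(runif(30000, -100, 0))
#' @export
criterion_a2_probabilities <- function(change_draws,
                                       thresholds = c(CR = 80, EN = 50,
                                                      VU = 30)) {
  if (length(change_draws) == 0 || anyNA(change_draws)) {
    stop_extrisk("change_draws must be non-empty and free of NA",
                 "extrisk_validation_error")
  }
  stopifnot(identical(names(thresholds), c("CR", "EN", "VU")),
            all(diff(thresholds) < 0))
  decline <- -change_draws
  tibble(
    category = c("CR", "EN", "VU", "LC_or_NT"),
    probability = c(
      mean(decline >= thresholds[["CR"]]),
      mean(decline >= thresholds[["EN"]] & decline < thresholds[["CR"]]),
      mean(decline >= thresholds[["VU"]] & decline < thresholds[["EN"]]),
      mean(decline < thresholds[["VU"]])
    )
  )
}

#' Assign a Red List category from A2 probabilities
#'
#' The category with the highest posterior probability wins, with ties
#' broken toward the more threatened category. When `LC_or_NT` wins, the
#' species is Least Concern only when its median decline lies below the
#' lower edge of `nt_band`; otherwise it is Near Threatened (approaching
#' — or, for a median beyond the band while the probability mass still
#' favours `LC_or_NT`, already brushing — the Vulnerable threshold). The
#' band's upper edge is where the Vulnerable threshold takes over on the
#' median; keeping NT beyond it preserves monotonicity: shifting the
#' whole posterior further downward can never yield a less threatened
#' category.
#'
#' @param probs output of [criterion_a2_probabilities()] (or a tibble with
#'   `category` and `probability` in the order CR, EN, VU, LC_or_NT).
#' @param median_change median percent change (negative = decline).
#' @param nt_band percent-decline interval `[lower, upper)` mapped to NT.
#' @return One of `"CR"`, `"EN"`, `"VU"`, `"NT"`, `"LC"`.
#' @export
assign_category <- function(probs, median_change, nt_band = c(20, 30)) {
  stopifnot(identical(probs$category, c("CR", "EN", "VU", "LC_or_NT")),
            abs(sum(probs$probability) - 1) < 1e-9)
  top <- probs$category[which.max(probs$probability)]
  if (top != "LC_or_NT") return(top)
  decline <- -median_change
  if (decline >= nt_band[1]) "NT" else "LC"
}

#' Assess decline over three generation lengths
#'
#' Bundles the posterior summary, Criterion A2 category probabilities, and
#' the assigned category for one species into a single row. A modeled
#' category is never silently altered: an expert `override` is recorded
#' alongside it and becomes the final category.
#'
#' @param change_draws posterior draws of percent change over three
#'   generation lengths (e.g. from [change_over_3gl()]).
#' @param three_gl_years the assessment window, in years.
#' @param nt_band passed to [assign_category()].
#' @param override optional expert-assigned Red List category replacing
#'   the modeled one in `final_category`.
#' @return A one-row tibble: median and 95% HPD of change, the four
#'   category probabilities (`p_cr`, `p_en`, `p_vu`, `p_lcnt`), and the
#'   modeled, override and final categories.
#' @export
assess_decline <- function(change_draws, three_gl_years,
                           nt_band = c(20, 30), override = NULL) {
  smry <- summarize_change(change_draws)
  probs <- criterion_a2_probabilities(change_draws)
  modeled <- assign_category(probs, smry$median_change, nt_band)
  if (!is.null(override) &&
      !override %in% c(threatened_categories, "NT", "LC")) {
    stop_extrisk(paste0("invalid override category '", override, "'"),
                 "extrisk_validation_error")
  }
  tibble(
    three_gl_years = three_gl_years,
    median_change = smry$median_change,
    hpd_lower = smry$hpd_lower, hpd_upper = smry$hpd_upper,
    p_cr = probs$probability[1], p_en = probs$probability[2],
    p_vu = probs$probability[3], p_lcnt = probs$probability[4],
    modeled_category = modeled,
    override_category = override %||% NA_character_,
    final_category = override %||% modeled
  )
}

#' Read a life-history table
#'
#' @param path CSV with columns `latin_binomial`, `max_age`,
#'   `age_at_maturity`, and optionally `z` (defaulting to 0.5).
#' @return A tibble with an added `gl` column of generation lengths.
#' @export
read_life_history <- function(path) {
  if (!file.exists(path)) {
    stop_extrisk(paste0("file not found: ", path), "extrisk_io_error")
  }
  lh <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("latin_binomial", "max_age", "age_at_maturity")
  missing <- setdiff(needed, names(lh))
  if (length(missing) > 0 || nrow(lh) == 0) {
    stop_extrisk(paste0("life-history table empty or missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "extrisk_format_error")
  }
  if (!"z" %in% names(lh)) lh$z <- 0.5
  lh |>
    mutate(gl = generation_length(.data$max_age, .data$age_at_maturity,
                                  .data$z)) |>
    as_tibble()
}
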