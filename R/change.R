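# Posterior percent change in abundance over a window, and over three
# generation lengths (extrapolating beyond the fitted span when needed).

mu_at_year <- function(fit, year) {
  span <- range(fit$years)
  if (year < span[1] || year > span[2]) {
    stop_extrisk(paste0("year ", year, " outside the fitted span ",
                        span[1], "-", span[2],
                        " (use change_over_3gl for extrapolation)"),
                 "extrisk_window_error")
  }
  j <- year - span[1] + 1
  lo <- floor(j)
  frac <- j - lo
  if (frac == 0) {
    fit$mu_draws[, lo]
  } else {
    # non-integer window start: interpolate log abundance between years
    (1 - frac) * fit$mu_draws[, lo] + frac * fit$mu_draws[, lo + 1]
  }
}

#' Posterior percent change between two fitted years
#'
#' For each posterior draw, the percent change in abundance
#' `100 * (exp(mu_end) - exp(mu_start)) / exp(mu_start)`.
#'
#' @param fit a [fit_trend()] object.
#' @param start_year,end_year years within the fitted span,
#'   `start_year < end_year`.
#' @return Numeric vector of per-draw percent changes; summarize with
#'   [summarize_change()].
#' @export
change_over_window <- function(fit, start_year, end_year) {
  stopifnot(inherits(fit, "trend_fit"))
  if (start_year >= end_year) {
    stop_extrisk("start_year must precede end_year", "extrisk_window_error")
  }
  100 * (exp(mu_at_year(fit, end_year) - mu_at_year(fit, start_year)) - 1)
}

#' Posterior percent change over three generation lengths
#'
#' The assessment window is the `three_gl_years` ending at the last fitted
#' year. When the window lies within the fitted span the change is read
#' off the latent trajectory ([change_over_window()]). When three
#' generation lengths exceed the observed span, the change is extrapolated
#' per posterior draw from that draw's mean annual log rate:
#' `100 * (exp(rbar * three_gl_years) - 1)` — a deterministic within-draw
#' extrapolation of the smooth exponential trend.
#'
#' @param fit a [fit_trend()] object.
#' @param three_gl_years three generation lengths, in years (> 0).
#' @return Numeric vector of per-draw percent changes.
#' @export
change_over_3gl <- function(fit, three_gl_years) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!is.numeric(three_gl_years) || three_gl_years <= 0) {
    stop_extrisk("three_gl_years must be a positive number",
                 "extrisk_validation_error")
  }
  last <- max(fit$years)
  start <- last - three_gl_years
  if (start >= min(fit$years)) {
    change_over_window(fit, start, last)
  } else {
    100 * (exp(fit$rbar_draws * three_gl_years) - 1)
  }
}

#' Summarize a posterior of percent change
#'
#' @param change_draws numeric vector of per-draw percent changes.
#' @param mass posterior mass of the HPD interval.
#' @return One-row tibble: `median_change`, `hpd_lower`, `hpd_upper`.
#' @export
summarize_change <- function(change_draws, mass = 0.95) {
  if (length(change_draws) == 0) {
    stop_extrisk("no change draws to summarize", "extrisk_validation_error")
  }
  if (length(unique(change_draws)) == 1) {
    hpd <- rep(change_draws[1], 2)
  } else {
    hpd <- hpd_interval(change_draws, mass)
  }
  tibble(median_change = median(change_draws),
         hpd_lower = hpd[1], hpd_upper = hpd[2])
}
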