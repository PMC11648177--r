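# Posterior diagnostics: Geweke stationarity z-score, highest posterior
# density intervals, and posterior predictive checks.

# Spectral density of a chain at frequency zero, estimated from an AR
# model with AIC-selected order (the standard estimator used by MCMC
# stationarity diagnostics). Falls back to the sample variance when the
# selected order is zero.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1, 20),
                   method = "yule-walker")
  if (fit$order == 0) v else fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke stationarity diagnostic
#'
#' Compares the mean of an early window of a chain with the mean of a late
#' window via a z-score whose variance terms are spectral-density-at-zero
#' estimates (so autocorrelation is accounted for). Under stationarity the
#' z-score is approximately standard normal; a small p-value indicates the
#' chain has not converged.
#'
#' @param chain numeric vector of sequential MCMC draws (length >= 100).
#' @param first_frac fraction of the chain in the early window.
#' @param last_frac fraction of the chain in the late window.
#' @return A list with elements `z` (the z-score) and `p` (two-sided
#'   p-value from the standard normal).
#' @examples
#' geweke_z(rnorm(5000))
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  n <- length(chain)
  if (n < 100) {
    stop_extrisk("Geweke diagnostic needs a chain of at least 100 draws",
                 "extrisk_validation_error")
  }
  if (stats::var(chain) == 0) {
    stop_extrisk("Geweke diagnostic undefined for a zero-variance chain",
                 "extrisk_undefined_error")
  }
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1, n)]
  s_a <- spectrum0_ar(a)
  s_b <- spectrum0_ar(b)
  if (s_a == 0 && s_b == 0) {
    stop_extrisk("Geweke diagnostic undefined: degenerate window variances",
                 "extrisk_undefined_error")
  }
  z <- (mean(a) - mean(b)) / sqrt(s_a / length(a) + s_b / length(b))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the empirical distribution
#' containing the requested posterior mass: among all windows of
#' `ceiling(mass * n)` inter-draw steps over the sorted sample, the
#' narrowest is returned.
#'
#' @param draws numeric vector of posterior draws (length >= 2).
#' @param mass posterior mass in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(10000))
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 2) {
    stop_extrisk("HPD interval needs at least 2 draws",
                 "extrisk_validation_error")
  }
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  gap <- max(1L, min(n - 1L, as.integer(ceiling(mass * n))))
  widths <- x[seq.int(1L + gap, n)] - x[seq_len(n - gap)]
  i <- which.min(widths)
  c(x[i], x[i + gap])
}

#' Posterior predictive check of a trend fit
#'
#' Draws replicated observations from the joint posterior predictive
#' distribution (latent state plus catchability offset plus observation
#' noise, per posterior draw) and compares them with the data. An
#' observation is flagged when it falls outside the central 95% of its
#' predictive distribution. For each observed index-year the credible
#' interval of the fitted trajectory is also compared against the
#' predictive interval: the fit passes overall when the fitted band lies
#' within the predictive band everywhere.
#'
#' @param fit a [fit_trend()] object.
#' @param mass central predictive mass used for flagging.
#' @param seed integer seed for the replicate noise draws (defaults to the
#'   fit's sampler seed, so the check is reproducible).
#' @return A tibble with one row per observation: `p_exceed` (fraction of
#'   replicated values above the observation), `flagged`, the predictive
#'   and fitted interval bounds on the log scale, and `band_ok`. The
#'   overall pass indicator is the attribute `band_within` (and
#'   `prop_flagged` records the flagged fraction).
#' @export
posterior_predictive_check <- function(fit, mass = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  seed <- seed %||% fit$settings$seed
  lo_q <- (1 - mass) / 2
  hi_q <- 1 - lo_q
  n_draws <- length(fit$rbar_draws)
  rows <- with_seed(seed + 104729L, {
    purrr::map_dfr(seq_len(nrow(fit$data)), function(k) {
      obs <- fit$data[k, ]
      i <- match(obs$index_id, fit$index_ids)
      j <- match(obs$year, fit$years)
      mean_log <- fit$logq_draws[, i] + fit$mu_draws[, j]
      rep_log <- mean_log + rnorm(n_draws, 0, sqrt(fit$obs_var_draws[, i]))
      fit_band <- quantile(mean_log, c(lo_q, hi_q), names = FALSE)
      pred_band <- quantile(rep_log, c(lo_q, hi_q), names = FALSE)
      p_exceed <- mean(rep_log > log(obs$value))
      tibble(
        index_id = obs$index_id, year = obs$year, value = obs$value,
        p_exceed = p_exceed,
        flagged = p_exceed < lo_q | p_exceed > hi_q,
        pred_lower = pred_band[1], pred_upper = pred_band[2],
        fit_lower = fit_band[1], fit_upper = fit_band[2],
        band_ok = fit_band[1] >= pred_band[1] & fit_band[2] <= pred_band[2]
      )
    })
  })
  attr(rows, "prop_flagged") <- mean(rows$flagged)
  attr(rows, "band_within") <- all(rows$band_ok)
  rows
}
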