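# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed summary values in Red List
#' reporting use conventional half-up rounding (e.g. 18.571 -> 18.6 at one
#' decimal), so reporting paths go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Seed-scoped evaluation: all package randomness flows through here so the
# caller's RNG state is never disturbed and identical seeds give identical
# output.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_extrisk <- function(msg, class) {
  abort(msg, class = c(class, "extrisk_error"))
}
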