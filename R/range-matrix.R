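# Species x country range-proportion matrices. Stored wide: first column
# latin_binomial, one numeric column per country, cells = proportion of the
# species' global range falling inside that country's EEZ. Rows of regional
# endemics sum to 1; species extending beyond the region may sum to less.

validate_range_matrix <- function(ranges, tol = 1e-9) {
  if (!"latin_binomial" %in% names(ranges)) {
    stop_extrisk("range matrix needs a latin_binomial column",
                 "extrisk_format_error")
  }
  countries <- setdiff(names(ranges), "latin_binomial")
  if (length(countries) == 0) {
    stop_extrisk("range matrix has no country columns", "extrisk_format_error")
  }
  mat <- as.matrix(ranges[countries])
  if (!is.numeric(mat) || anyNA(mat)) {
    stop_extrisk("range proportions must all be numeric and non-missing",
                 "extrisk_validation_error")
  }
  bad <- mat < 0 | mat > 1 + tol
  if (any(bad)) {
    sp <- ranges$latin_binomial[which(rowSums(bad) > 0)[1]]
    stop_extrisk(paste0("range proportion outside [0, 1] for species '",
                        sp, "'"),
                 "extrisk_validation_error")
  }
  sums <- rowSums(mat)
  if (any(sums > 1 + tol)) {
    sp <- ranges$latin_binomial[which(sums > 1 + tol)[1]]
    stop_extrisk(paste0("range proportions for species '", sp,
                        "' sum to ", signif(max(sums), 4), " (> 1)"),
                 "extrisk_validation_error")
  }
  invisible(ranges)
}

#' Read a species-by-country range-proportion matrix
#'
#' @param path CSV path; first column `latin_binomial`, remaining columns
#'   one per country, cells the proportion of the species' global range in
#'   that country's Exclusive Economic Zone.
#' @return A validated tibble (all cells in `[0, 1]`, each row summing to
#'   at most 1).
#' @export
read_range_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_extrisk(paste0("file not found: ", path), "extrisk_io_error")
  }
  ranges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_range_matrix(ranges)
  as_tibble(ranges)
}

#' Write a range-proportion matrix
#'
#' Inverse of [read_range_matrix()].
#'
#' @param ranges range matrix tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_range_matrix <- function(ranges, path) {
  validate_range_matrix(ranges)
  readr::write_csv(ranges, path, progress = FALSE)
  invisible(path)
}

# Long view used by the RLI computations: latin_binomial, country, p.
range_matrix_long <- function(ranges) {
  validate_range_matrix(ranges)
  tidyr::pivot_longer(ranges, -"latin_binomial",
                      names_to = "country", values_to = "p")
}
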