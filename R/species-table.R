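# Species assessment tables: Red List categories per epoch, threat codes,
# and tallies. A species table is an ordinary tibble with one row per
# species; category columns are named cat_<epoch> (e.g. cat_2020).

#' IUCN Red List category codes
#'
#' The eight category codes in decreasing order of extinction risk:
#' Extinct (EX), Extinct in the Wild (EW), Critically Endangered (CR),
#' Endangered (EN), Vulnerable (VU), Near Threatened (NT), Least Concern
#' (LC), and Data Deficient (DD). CR, EN and VU are collectively termed
#' "threatened".
#'
#' @format A character vector of length eight.
#' @export
red_list_categories <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD")

#' @rdname red_list_categories
#' @export
threatened_categories <- c("CR", "EN", "VU")

cat_column <- function(epoch) paste0("cat_", epoch)

assert_epoch <- function(table, epoch) {
  col <- cat_column(epoch)
  if (!col %in% names(table)) {
    stop_extrisk(
      paste0("epoch ", epoch, " not present in table (no column '", col, "')"),
      "extrisk_lookup_error"
    )
  }
  col
}

validate_categories <- function(x, species, what) {
  bad <- !is.na(x) & !x %in% red_list_categories
  if (any(bad)) {
    stop_extrisk(
      paste0(
        "unrecognised Red List category '", x[bad][1], "' for species '",
        species[bad][1], "' in column ", what
      ),
      "extrisk_validation_error"
    )
  }
  invisible(x)
}

#' Read a species assessment table
#'
#' Reads a CSV with one row per species and one Red List category column
#' per assessment epoch (`cat_<epoch>`). Categories must be the two-letter
#' IUCN codes; threat codes are a semicolon-separated list of dotted IUCN
#' threat-classification identifiers (e.g. `"5;5.4"`).
#'
#' @param path path to a CSV file with columns `latin_binomial`,
#'   `common_name`, `order`, `family`, one `cat_<epoch>` column per epoch,
#'   and optionally `newly_described`, `threat_codes`, `change_type`.
#' @param epochs integer vector of assessment epochs that must be present.
#' @return A tibble with one row per species, classed for validation.
#' @examples
#' tbl <- read_species_table(extrisk_example("swio_endemics.csv"))
#' tally_categories(tbl, 2020)
#' @export
read_species_table <- function(path, epochs = c(1980, 2005, 2020)) {
  if (!file.exists(path)) {
    stop_extrisk(paste0("file not found: ", path), "extrisk_io_error")
  }
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop_extrisk(paste0("cannot parse CSV: ", conditionMessage(e)),
                   "extrisk_format_error")
    }
  )
  if (nrow(tbl) == 0 && ncol(tbl) == 0) {
    stop_extrisk("empty species table file", "extrisk_format_error")
  }
  needed <- c("latin_binomial", cat_column(epochs))
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    stop_extrisk(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 "extrisk_format_error")
  }
  if (anyNA(tbl$latin_binomial) || any(tbl$latin_binomial == "")) {
    stop_extrisk("latin_binomial must be non-empty for every row",
                 "extrisk_validation_error")
  }
  if (anyDuplicated(tbl$latin_binomial)) {
    dup <- tbl$latin_binomial[duplicated(tbl$latin_binomial)][1]
    stop_extrisk(paste0("duplicate latin_binomial: ", dup),
                 "extrisk_validation_error")
  }
  for (ep in epochs) {
    col <- cat_column(ep)
    tbl[[col]] <- as.character(tbl[[col]])
    if (anyNA(tbl[[col]])) {
      miss <- tbl$latin_binomial[is.na(tbl[[col]])][1]
      stop_extrisk(paste0("missing category for species '", miss,
                          "' at epoch ", ep),
                   "extrisk_validation_error")
    }
    validate_categories(tbl[[col]], tbl$latin_binomial, col)
  }
  if (!"threat_codes" %in% names(tbl)) tbl$threat_codes <- NA_character_
  tbl$threat_codes <- as.character(tbl$threat_codes)
  as_tibble(tbl)
}

#' Write a species assessment table
#'
#' Inverse of [read_species_table()]; `read(write(x))` returns `x`.
#'
#' @param table a species table tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' The package ships the published Red List assessment table for the 70
#' shark and ray species endemic to the southwest Indian Ocean region
#' (`"swio_endemics.csv"`): original, backcast (1980 and 2005) and current
#' (2020) categories, plus threat codes and genuine/non-genuine change
#' labels. Threat-code attribution for individual species is reconstructed
#' from the published aggregate counts (all 20 threatened and Near
#' Threatened species carry fishing codes 5/5.4, seven carry climate code
#' 11, three carry development/pollution codes 1/9) and is exact only for
#' the species named in the source text.
#'
#' @param file file name; with no argument, lists available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' extrisk_example()
#' @export
extrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "extrisk"))
  } else {
    path <- system.file("extdata", file, package = "extrisk", mustWork = FALSE)
    if (path == "") {
      stop_extrisk(paste0("no packaged file '", file, "'"), "extrisk_io_error")
    }
    path
  }
}

#' Tally Red List categories at one epoch
#'
#' @param table a species table.
#' @param epoch an assessment epoch present in the table.
#' @return A tibble with columns `category` and `n`, one row per category
#'   code (zero counts included), ordered from EX to DD. Counts sum to the
#'   number of species.
#' @export
tally_categories <- function(table, epoch) {
  col <- assert_epoch(table, epoch)
  counts <- table(factor(table[[col]], levels = red_list_categories))
  tibble(category = red_list_categories, n = as.integer(counts))
}

#' Percentage of species in a set of categories
#'
#' Reported with conventional half-up rounding at one decimal, matching
#' standard Red List summary reporting (13 of 70 species -> 18.6).
#'
#' @inheritParams tally_categories
#' @param categories character vector of category codes, e.g.
#'   `threatened_categories`.
#' @return A single percentage, rounded half-up to one decimal.
#' @export
percent_in_categories <- function(table, epoch, categories) {
  col <- assert_epoch(table, epoch)
  if (nrow(table) == 0) {
    stop_extrisk("cannot compute a percentage of an empty table",
                 "extrisk_undefined_error")
  }
  stopifnot(all(categories %in% red_list_categories))
  round_half_up(100 * sum(table[[col]] %in% categories) / nrow(table), 1)
}

parse_threat_codes <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  unique(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
}

#' Tally threat codes across a category subset
#'
#' Counts, for each distinct IUCN threat-classification code, the number of
#' species in the given categories that carry it. A species carrying a code
#' is counted once for that code regardless of repetition.
#'
#' @inheritParams percent_in_categories
#' @param categories category codes delimiting the species subset
#'   (default: threatened plus Near Threatened).
#' @return A tibble with columns `threat_code` and `n`, sorted by
#'   descending count then code.
#' @export
tally_threat_codes <- function(table, epoch = 2020,
                               categories = c(threatened_categories, "NT")) {
  col <- assert_epoch(table, epoch)
  sub <- table[table[[col]] %in% categories, , drop = FALSE]
  codes <- unlist(lapply(sub$threat_codes, parse_threat_codes))
  if (length(codes) == 0) {
    return(tibble(threat_code = character(0), n = integer(0)))
  }
  counts <- sort(table(codes), decreasing = TRUE)
  tibble(threat_code = names(counts), n = as.integer(counts)) |>
    arrange(desc(.data$n), .data$threat_code)
}
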