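test_that("global RLI reproduces the published regional values", {
  tbl <- fixture_table()
  expect_equal(round(global_rli(tbl, 1980), 3), 0.996)
  expect_equal(round(global_rli(tbl, 2005), 3), 0.917)
  expect_equal(round(global_rli(tbl, 2020), 3), 0.849)
})

test_that("RLI attains its bounds at all-LC and all-EX tables", {
  all_lc <- tibble::tibble(latin_binomial = paste("Sp", 1:10),
                           cat_2020 = "LC")
  expect_equal(global_rli(all_lc, 2020), 1)
  all_ex <- tibble::tibble(latin_binomial = paste("Sp", 1:10),
                           cat_2020 = "EX")
  expect_equal(global_rli(all_ex, 2020), 0)
  all_dd <- tibble::tibble(latin_binomial = paste("Sp", 1:4),
                           cat_2020 = "DD")
  expect_error(global_rli(all_dd, 2020), class = "extrisk_undefined_error")
})

test_that("uplisting one species moves global RLI by exactly 1/(w_ex N)", {
  steps <- c("LC", "NT", "VU", "EN", "CR")
  withr::with_seed(8, {
    for (k in 1:10) {
      n <- sample(5:40, 1)
      tbl <- tibble::tibble(
        latin_binomial = paste("Sp", seq_len(n)),
        cat_2020 = sample(c(steps, "DD"), n, replace = TRUE)
      )
      non_dd <- which(tbl$cat_2020 %in% steps[-5])
      if (length(non_dd) == 0 ||
          !any(tbl$cat_2020 != "DD")) next
      before <- global_rli(tbl, 2020)
      i <- sample(non_dd, 1)
      tbl$cat_2020[i] <- steps[match(tbl$cat_2020[i], steps) + 1]
      after <- global_rli(tbl, 2020)
      n_assessed <- sum(tbl$cat_2020 != "DD")
      expect_equal(before - after, 1 / (5 * n_assessed))
    }
  })
})

test_that("a single all-containing country reduces to the global RLI", {
  tbl <- fixture_table()
  ranges <- tibble::tibble(latin_binomial = tbl$latin_binomial,
                           Everywhere = 1)
  for (ep in c(1980, 2005, 2020)) {
    expect_equal(country_rli(tbl, ep, ranges, "Everywhere"),
                 global_rli(tbl, ep))
  }
})

test_that("country RLI matches hand computation from the equation", {
  tbl <- tibble::tibble(latin_binomial = c("Sp a", "Sp b"),
                        cat_2020 = c("LC", "CR"))
  ranges <- tibble::tibble(latin_binomial = c("Sp a", "Sp b"),
                           X = c(1, 1), Y = c(0, 0))
  # both species entirely in X: 1 - (0 + 4) / (5 * 2) = 0.6
  expect_equal(country_rli(tbl, 2020, ranges, "X"), 0.6)
  expect_error(country_rli(tbl, 2020, ranges, "Y"),
               class = "extrisk_undefined_error")
  expect_error(country_rli(tbl, 2020, ranges, "Z"),
               class = "extrisk_lookup_error")
})

test_that("country RLI matches brute-force recomputation on random matrices", {
  w <- threat_weights()
  withr::with_seed(9, {
    for (k in 1:10) {
      tbl <- sim_species_table(seed = 50 + k, n_species = 10)
      ranges <- sim_range_matrix(seed = 60 + k, tbl$latin_binomial,
                                 countries = c("A", "B", "C"))
      cats <- setNames(tbl$cat_2020, tbl$latin_binomial)
      for (cn in c("A", "B", "C")) {
        keep <- cats[ranges$latin_binomial] != "DD"
        p <- ranges[[cn]][keep]
        ws <- w$weights[cats[ranges$latin_binomial][keep]]
        if (sum(p) == 0) next
        expect_equal(country_rli(tbl, 2020, ranges, cn),
                     1 - sum(ws * p) / (5 * sum(p)))
      }
    }
  })
})

test_that("uplisting an in-country species strictly decreases country RLI", {
  tbl <- sim_species_table(seed = 70, n_species = 12)
  ranges <- sim_range_matrix(seed = 71, tbl$latin_binomial,
                             countries = c("A", "B"))
  before <- country_rli(tbl, 2020, ranges, "A")
  i <- which(tbl$cat_2020 == "LC")[1]
  tbl$cat_2020[i] <- "EN"
  expect_lt(country_rli(tbl, 2020, ranges, "A"), before)
})

test_that("national responsibility normalizes the top country to one", {
  tbl <- tibble::tibble(latin_binomial = "Sp a", cat_2020 = "CR")
  ranges <- tibble::tibble(latin_binomial = "Sp a", X = 0.7, Y = 0.3)
  ncr <- national_responsibility(tbl, 2020, ranges)
  expect_equal(ncr$score[ncr$country == "X"], 1)
  expect_equal(round(ncr$score[ncr$country == "Y"], 3), 0.429)
  expect_equal(ncr$score_raw[ncr$country == "X"], 4 * 0.7)

  raw <- national_responsibility(tbl, 2020, ranges, normalize = FALSE)
  expect_equal(raw$score, raw$score_raw)
})

test_that("all-LC tables give zero responsibility with a warning", {
  tbl <- tibble::tibble(latin_binomial = c("Sp a", "Sp b"),
                        cat_2020 = "LC")
  ranges <- sim_range_matrix(seed = 2, tbl$latin_binomial, c("X", "Y"))
  expect_warning(
    ncr <- national_responsibility(tbl, 2020, ranges),
    class = "extrisk_normalization_warning"
  )
  expect_true(all(ncr$score == 0))
})

test_that("a country holding no ranges scores zero responsibility", {
  tbl <- tibble::tibble(latin_binomial = "Sp a", cat_2020 = "VU")
  ranges <- tibble::tibble(latin_binomial = "Sp a", X = 1, Y = 0)
  ncr <- national_responsibility(tbl, 2020, ranges)
  expect_equal(ncr$score[ncr$country == "Y"], 0)
})

test_that("the RLI series reproduces the published epoch sequence", {
  tbl <- fixture_table()
  series <- rli_series(tbl, c(1980, 2005, 2020))
  expect_equal(round(series$rli, 3), c(0.996, 0.917, 0.849))
  expect_equal(series$n_assessed, rep(53L, 3))
})

test_that("RLI series is constant for stasis, decreasing for uplisting", {
  all_lc <- tibble::tibble(latin_binomial = paste("Sp", 1:8),
                           cat_1980 = "LC", cat_2005 = "LC",
                           cat_2020 = "LC")
  expect_equal(rli_series(all_lc, c(1980, 2005, 2020))$rli, rep(1, 3))

  moved <- all_lc
  moved$cat_2005[1] <- "EN"
  moved$cat_2020[1] <- "CR"
  series <- rli_series(moved, c(1980, 2005, 2020))$rli
  expect_true(all(diff(series) < 0))
})

test_that("country RLI series values stay within [0, 1]", {
  tbl <- fixture_table()
  ranges <- sim_range_matrix(seed = 14, tbl$latin_binomial,
                             countries = c("South Africa", "Mozambique",
                                           "Madagascar"))
  series <- rli_series(tbl, c(1980, 2005, 2020), ranges = ranges)
  expect_true(all(series$rli >= 0 & series$rli <= 1))
  expect_s3_class(plot_rli(series), "ggplot")
})
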