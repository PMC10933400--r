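# Reading, variance normalization and record-selection rules.

write_demo_csv <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, p)
  p
}

test_that("variance measures are normalized to SD", {
  # SE -> SD and CI95 half-width -> SD; t_{0.975,24} = 2.0639 from tables
  expect_equal(sd_from_variance(10, "SD", 25), 10)
  expect_equal(sd_from_variance(2, "SE", 25), 10)
  expect_equal(sd_from_variance(4.128, "CI95", 25), 10, tolerance = 1e-3)
  expect_equal(sd_from_variance(4.128, "CI95", 25),
               4.128 * sqrt(25) / stats::qt(0.975, 24))
  expect_error(sd_from_variance(1, "IQR", 10), "unknown variance_type")
})

test_that("read_trait_table normalizes a mixed-variance file and rejects bad rows", {
  df <- tibble::tibble(
    order = "O1", family = "F1",
    species = c("Sp a", "Sp b", "Sp c", "Sp d", ""),
    male_mean = c(100, 100, 100, NA, 100),
    male_var = c(10, 2, 4.128, 10, 10),
    male_n = c(25, 25, 25, 25, 25),
    female_mean = c(90, 90, 90, 90, 90),
    female_var = c(10, 2, 4.128, 10, 10),
    female_n = c(25, 25, 25, 25, 25),
    variance_type = c("SD", "SE", "CI95", "SD", "SD")
  )
  p <- write_demo_csv(df)
  expect_message(rec <- read_trait_table(p, measure = "mass"), "rejected")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$male_sd, c(10, 10, 4.128 * 5 / stats::qt(0.975, 24)))
  rej <- attr(rec, "rejected")
  expect_equal(rej$row, c(4, 5))
  expect_match(rej$reason[1], "male_mean")
  expect_match(rej$reason[2], "species")
})

test_that("a dialect can map foreign column names", {
  df <- tibble::tibble(
    Ord = "O1", Fam = "F1", Binomial = "Sp a",
    male_mean = 10, male_sd = 1, male_n = 10,
    female_mean = 9, female_sd = 1, female_n = 10
  )
  p <- write_demo_csv(df)
  rec <- read_trait_table(p, dialect = c(order = "Ord", family = "Fam",
                                         species = "Binomial"))
  expect_equal(rec$species, "Sp a")
  expect_error(read_trait_table(p, dialect = c(order = "NotThere")),
               "absent")
})

test_that("inconsistent family-to-order mapping is refused", {
  df <- make_records(2)
  df$order <- c("O1", "O2")  # same family in both
  p <- write_demo_csv(df)
  expect_error(read_trait_table(p), "more than one order")
})

test_that("trait table round-trips through CSV unchanged", {
  rec <- make_records(6,
                      male_mean = c(3.14159, 1e6, 0.73, 12.5, 88.1, 5) / 7,
                      male_n = c(2L, 9L, 10L, 50L, 7L, 120L))
  p <- write_demo_csv(rec)
  back <- suppressMessages(read_trait_table(p))
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("best-population selection keeps one record per species", {
  one <- make_records(1)
  expect_equal(nrow(select_best_population(one)), 1)

  two <- make_records(2, species = c("Sp x", "Sp x"),
                      male_n = c(12L, 30L), female_n = c(40L, 30L))
  expect_equal(select_best_population(two)$male_n, 30L)

  # min-n tie (20, 20, 15); totals (45, 50, 60): total breaks the tie
  three <- make_records(3, species = "Sp y",
                        male_n = c(25L, 30L, 45L),
                        female_n = c(20L, 20L, 15L))
  picked <- select_best_population(three)
  expect_equal(picked$male_n + picked$female_n, 50L)

  # full tie falls back to input order
  tied <- make_records(2, species = "Sp z", population = c("a", "b"))
  expect_equal(select_best_population(tied)$population, "a")
})

test_that("selection output size equals the number of distinct species", {
  set.seed(11)
  rec <- make_records(40,
                      species = sprintf("Sp %d", sample(1:12, 40, TRUE)),
                      male_n = sample(2:80, 40, TRUE),
                      female_n = sample(2:80, 40, TRUE))
  out <- select_best_population(rec)
  expect_equal(nrow(out), length(unique(rec$species)))
  # chosen record maximizes min(male_n, female_n) within species
  best <- tapply(pmin(rec$male_n, rec$female_n), rec$species, max)
  expect_equal(as.integer(pmin(out$male_n, out$female_n)),
               as.integer(best[out$species]))
})

test_that("minimum-n filter obeys the both-sexes rule and is monotone", {
  rec <- make_records(3, male_n = c(9L, 9L, 8L), female_n = c(9L, 8L, 20L))
  expect_equal(nrow(suppressMessages(filter_min_n(rec, 1))), 3)
  kept <- suppressMessages(filter_min_n(rec, 9))
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "n_removed"), 2L)

  set.seed(5)
  rec <- make_records(20, male_n = sample(1:30, 20, TRUE),
                      female_n = sample(1:30, 20, TRUE))
  survivors <- suppressMessages(filter_min_n(rec, 9))
  expect_equal(survivors$species,
               rec$species[rec$male_n >= 9 & rec$female_n >= 9])
  # idempotent, and raising n_min never adds records
  expect_equal(nrow(suppressMessages(filter_min_n(survivors, 9))),
               nrow(survivors))
  sizes <- vapply(1:30, function(k) {
    nrow(suppressMessages(filter_min_n(rec, k)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("richness table validation enforces uniqueness and counts", {
  rt <- tibble::tibble(order = c("O1", "O1"), family = c("F1", "F2"),
                       species_count = c(10, 3))
  expect_silent(validate_richness_table(rt))
  expect_error(validate_richness_table(rt[c(1, 1), ]), "more than once")
  rt$species_count[1] <- 0
  expect_error(validate_richness_table(rt), ">= 1")
})
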