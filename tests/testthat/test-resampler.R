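# Species-richness-weighted stratified resampling.

# classified-species table with fixed classes, one row per species
classified_fixture <- function(order, family, class) {
  k <- length(class)
  tibble::tibble(
    order = order, family = family,
    species = sprintf("Sp %03d", seq_len(k)),
    class = factor(class, levels = c("monomorphic", "male_biased",
                                     "female_biased"))
  )
}

test_that("quotas round half away from zero", {
  expect_identical(compute_quota(10, 0.05), 1L)
  expect_identical(compute_quota(9, 0.05), 0L)
  expect_identical(compute_quota(51, 0.05), 3L)
  expect_identical(compute_quota(50, 0.05), 3L)  # 2.5 rounds up
  expect_identical(compute_quota(c(20, 100), 0.05), c(1L, 5L))
})

test_that("an all-monomorphic dataset gives overall rates (1, 0, 0)", {
  cl <- classified_fixture("O1", "F1", rep("monomorphic", 5))
  rt <- tibble::tibble(order = "O1", family = "F1", species_count = 40)
  r <- resample_rates(cl, rt, fraction = 0.05, reps = 50, seed = 99)
  ov <- r[r$stratum == "overall", ]
  expect_equal(ov$rate_mono, 1)
  expect_equal(ov$rate_male, 0)
  expect_equal(ov$sd_mono, 0)
})

test_that("Monte-Carlo rates match the exact without-replacement expectation", {
  # one family, quota 2 of 4 rows (2 male-biased, 2 monomorphic): the
  # exact expected male rate, by enumerating all C(4,2) subsets, is 0.5
  cl <- classified_fixture("O1", "F1", c("male_biased", "male_biased",
                                         "monomorphic", "monomorphic"))
  subsets <- utils::combn(4, 2)
  exact <- mean(apply(subsets, 2, function(i) {
    mean(cl$class[i] == "male_biased")
  }))
  expect_equal(exact, 0.5)

  rt <- tibble::tibble(order = "O1", family = "F1", species_count = 40)
  r <- resample_rates(cl, rt, fraction = 0.05, reps = 1000, seed = 7)
  ov <- r[r$stratum == "overall", ]
  mc_se <- ov$sd_male / sqrt(ov$reps_used)
  expect_lt(abs(ov$rate_male - exact), 3 * mc_se + 1e-12)
})

test_that("internally homogeneous strata give deterministic rates", {
  cl <- classified_fixture(
    order = rep(c("O1", "O2"), c(3, 5)),
    family = rep(c("F1", "F2"), c(3, 5)),
    class = rep(c("female_biased", "male_biased"), c(3, 5)))
  rt <- tibble::tibble(order = c("O1", "O2"), family = c("F1", "F2"),
                       species_count = c(20, 60))  # quotas 1 and 3
  r <- resample_rates(cl, rt, fraction = 0.05, reps = 200, seed = 1,
                      min_stratum_species = 10)
  ov <- r[r$stratum == "overall", ]
  expect_equal(ov$rate_mono, 0)
  expect_equal(ov$rate_male, 0.75)
  expect_equal(ov$rate_female, 0.25)
  expect_equal(ov$sd_male, 0)
  expect_equal(r[r$stratum == "O1", ]$rate_female, 1)
})

test_that("rates sum to one and identical seeds reproduce bit-identical output", {
  set.seed(88)
  cl <- classified_fixture(
    order = rep(c("O1", "O2"), each = 10),
    family = rep(c("F1", "F2", "F3", "F4"), each = 5),
    class = sample(c("monomorphic", "male_biased", "female_biased"),
                   20, TRUE))
  rt <- tibble::tibble(order = rep(c("O1", "O2"), each = 2),
                       family = c("F1", "F2", "F3", "F4"),
                       species_count = c(45, 80, 120, 15))
  r1 <- suppressWarnings(
    resample_rates(cl, rt, fraction = 0.05, reps = 300, seed = 42))
  r2 <- suppressWarnings(
    resample_rates(cl, rt, fraction = 0.05, reps = 300, seed = 42))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  sums <- r1$rate_mono + r1$rate_male + r1$rate_female
  expect_true(all(abs(sums - 1) < 1e-9))
  r3 <- suppressWarnings(
    resample_rates(cl, rt, fraction = 0.05, reps = 300, seed = 43))
  expect_false(identical(r1$rate_mono, r3$rate_mono))
})

test_that("quotas equal to availability reduce to plain class frequencies", {
  set.seed(12)
  cl <- classified_fixture(
    order = "O1", family = rep(c("F1", "F2"), each = 6),
    class = sample(c("monomorphic", "male_biased", "female_biased"),
                   12, TRUE))
  # 5% of 120 = 6 = all available rows in each family
  rt <- tibble::tibble(order = "O1", family = c("F1", "F2"),
                       species_count = c(120, 120))
  r <- resample_rates(cl, rt, fraction = 0.05, reps = 50, seed = 3)
  ov <- r[r$stratum == "overall", ]
  expect_equal(ov$rate_mono, mean(cl$class == "monomorphic"))
  expect_equal(ov$rate_male, mean(cl$class == "male_biased"))
  expect_equal(ov$sd_mono, 0)  # every repetition takes the same rows
})

test_that("orders made only of small families are pooled into one stratum", {
  # four families of < 10 species each; order total 10 -> quota 1:
  # exactly one row is drawn per repetition, so per-rep rates are 0/1
  cl <- classified_fixture(
    order = "Pilosa_like", family = c("F1", "F1", "F2", "F3"),
    class = c("male_biased", "male_biased", "monomorphic", "monomorphic"))
  rt <- tibble::tibble(order = "Pilosa_like",
                       family = c("F1", "F2", "F3", "F4"),
                       species_count = c(3, 3, 2, 2))
  r <- resample_rates(cl, rt, fraction = 0.05, reps = 400, seed = 5,
                      pool_small_family_orders = TRUE)
  ov <- r[r$stratum == "overall", ]
  # one Bernoulli row per rep: SD of a 0/1 rate is sqrt(p(1-p))-ish, not 0
  expect_equal(ov$rate_mono + ov$rate_male, 1)
  expect_gt(ov$sd_male, 0.3)
  expect_equal(abs(ov$rate_male - 0.5) < 0.1, TRUE)  # 2 of 4 rows male

  # without pooling every family quota rounds to 0 and nothing is sampled
  expect_error(
    resample_rates(cl, rt, fraction = 0.05, reps = 10, seed = 5,
                   pool_small_family_orders = FALSE),
    "quota 0")
})

test_that("missing richness entries and under-coverage are reported", {
  cl <- classified_fixture("O1", "F_unknown", c("monomorphic", "male_biased"))
  rt <- tibble::tibble(order = "O1", family = "F1", species_count = 40)
  expect_error(resample_rates(cl, rt), "absent from the richness table")

  cl2 <- classified_fixture("O1", "F1", "monomorphic")
  rt2 <- tibble::tibble(order = "O1", family = "F1", species_count = 100)
  expect_warning(r <- resample_rates(cl2, rt2, fraction = 0.05, reps = 20,
                                     seed = 2),
                 "quota exceeds available")
  expect_equal(r[r$stratum == "overall", ]$rate_mono, 1)
})

test_that("per-order rows appear only for orders of sufficient richness", {
  cl <- classified_fixture(
    order = c("Big", "Big", "Small"), family = c("FB", "FB", "FS"),
    class = c("male_biased", "monomorphic", "female_biased"))
  rt <- tibble::tibble(order = c("Big", "Small"), family = c("FB", "FS"),
                       species_count = c(60, 9))
  r <- suppressWarnings(resample_rates(cl, rt, fraction = 0.2, reps = 50,
                                       seed = 9, min_stratum_species = 10))
  expect_setequal(r$stratum, c("overall", "Big"))
  rep_tbl <- rate_report(r)
  expect_equal(nrow(rep_tbl), 2)
  expect_equal(rep_tbl$pct_monomorphic + rep_tbl$pct_male_biased +
                 rep_tbl$pct_female_biased, c(100, 100), tolerance = 0.2)
})

test_that("order-level stratification uses order totals", {
  cl <- classified_fixture(
    order = rep("O1", 4), family = c("F1", "F1", "F2", "F2"),
    class = rep("male_biased", 4))
  rt <- tibble::tibble(order = "O1", family = c("F1", "F2"),
                       species_count = c(150, 150))
  r <- resample_rates(cl, rt, fraction = 0.01, stratum_level = "order",
                      reps = 30, seed = 4)
  ov <- r[r$stratum == "overall", ]
  expect_equal(ov$rate_male, 1)
  expect_equal(attr(r, "config")$rows_per_rep, 3L)  # round(0.01 * 300)
})
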