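# Synthetic comparative datasets with known ground truth: a hierarchical
# taxonomy (orders -> families -> species), a true dimorphism class and
# effect size per species, and per-sex lognormal samples summarised to
# mean/SD/n rows, optionally split into season/site subgroups.

#' Simulate a sex-segregated comparative trait dataset
#'
#' Generates a taxonomy, assigns each species a true dimorphism class and
#' ratio, draws per-sex raw samples and emits their summary statistics,
#' so that every pipeline stage can be validated against known truth.
#'
#' Within-sex masses are lognormal (body masses are strictly positive and
#' span many orders of magnitude); the species' true mean for the larger
#' sex is the smaller sex's mean times the class's ratio, and each sex's
#' true SD is its mean times that sex's coefficient of variation.  Per-sex
#' sample sizes are drawn log-uniformly and include values below typical
#' admissibility cutoffs, so the minimum-n filter has work to do.  A
#' fraction of populations is split into 2–3 subgroups by partitioning the
#' raw sample, so pooled subgroup moments equal the full-sample moments
#' exactly.
#'
#' @param n_orders Number of orders.
#' @param families_per_order Length-2 integer range of families per order.
#' @param richness_per_family Length-2 range of true species counts per
#'   family (drawn log-uniformly).
#' @param sampled_fraction Share of each family's richness that appears in
#'   the dataset (at least one species per family), in (0, 1].
#' @param true_class_probs Probabilities of (monomorphic, male-biased,
#'   female-biased), summing to 1.
#' @param ratio_range_male,ratio_range_female Ranges of the larger/smaller
#'   mean ratio per class (drawn log-uniformly); defaults span the
#'   moderate-to-extreme ratios seen in mammals (up to 3.2 male-biased,
#'   1.4 female-biased).
#' @param cv_male,cv_female Within-sex coefficients of variation of mass.
#' @param n_range Length-2 range of per-sex sample sizes (log-uniform
#'   integers).
#' @param subgroup_split_prob Probability that a population's summaries
#'   are reported split into subgroups.
#' @param base_mass_range Length-2 log-uniform bounds of the smaller-sex
#'   mean mass, grams.
#' @param measure `"mass"` or `"length"` label for the emitted records.
#' @param seed Optional integer seed.
#' @return A list with elements `traits` (canonical trait tibble),
#'   `richness` (richness tibble), `truth` (per-species ground truth),
#'   `subgroups` (long tibble of split summaries, possibly empty) and
#'   `config`.
#' @export
simulate_ssd_data <- function(n_orders = 12,
                              families_per_order = c(3, 8),
                              richness_per_family = c(2, 120),
                              sampled_fraction = 0.25,
                              true_class_probs = c(monomorphic = 0.40,
                                                   male_biased = 0.45,
                                                   female_biased = 0.15),
                              ratio_range_male = c(1.05, 3.2),
                              ratio_range_female = c(1.05, 1.4),
                              cv_male = 0.15, cv_female = 0.12,
                              n_range = c(2, 120),
                              subgroup_split_prob = 0.10,
                              base_mass_range = c(4, 1e6),
                              measure = "mass",
                              seed = NULL) {
  stopifnot(n_orders >= 1,
            length(families_per_order) == 2, all(families_per_order >= 1),
            length(richness_per_family) == 2, all(richness_per_family >= 1),
            sampled_fraction > 0, sampled_fraction <= 1,
            length(true_class_probs) == 3, all(true_class_probs >= 0),
            abs(sum(true_class_probs) - 1) < 1e-8,
            all(ratio_range_male >= 1), all(ratio_range_female >= 1),
            cv_male > 0, cv_female > 0,
            length(n_range) == 2, n_range[1] >= 2,
            subgroup_split_prob >= 0, subgroup_split_prob <= 1,
            all(base_mass_range > 0))
  if (!is.null(seed)) set.seed(seed)

  rlogunif <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
  rint <- function(k, lo, hi) pmin(hi, pmax(lo, round(rlogunif(k, lo, hi))))

  # taxonomy
  fam_rows <- list(); sp <- 0L
  for (o in seq_len(n_orders)) {
    nf <- if (families_per_order[1] == families_per_order[2]) {
      families_per_order[1]
    } else {
      sample(seq(families_per_order[1], families_per_order[2]), 1)
    }
    for (f in seq_len(nf)) {
      rich <- as.integer(rint(1, richness_per_family[1],
                              richness_per_family[2]))
      fam_rows[[length(fam_rows) + 1]] <- tibble::tibble(
        order = sprintf("Order_%02d", o),
        family = sprintf("Family_%02d_%02d", o, f),
        species_count = rich,
        n_sampled = max(1L, as.integer(floor(sampled_fraction * rich + 0.5)))
      )
    }
  }
  fam <- dplyr::bind_rows(fam_rows)
  fam$n_sampled <- pmin(fam$n_sampled, fam$species_count)

  trait_rows <- list(); truth_rows <- list(); sub_rows <- list()
  classes <- .ssd_classes
  summarise_chunk <- function(v) {
    c(mean = mean(v), sd = if (length(v) >= 2) stats::sd(v) else 0,
      n = length(v))
  }

  for (i in seq_len(nrow(fam))) {
    for (s in seq_len(fam$n_sampled[i])) {
      sp <- sp + 1L
      species <- sprintf("Genus_%03d species_%04d", i, sp)
      cls <- sample(classes, 1, prob = true_class_probs)
      base <- rlogunif(1, base_mass_range[1], base_mass_range[2])
      ratio <- switch(cls,
        monomorphic = 1,
        male_biased = rlogunif(1, ratio_range_male[1], ratio_range_male[2]),
        female_biased = rlogunif(1, ratio_range_female[1],
                                 ratio_range_female[2]))
      mu_m <- if (cls == "female_biased") base else base * ratio
      mu_f <- if (cls == "female_biased") base * ratio else base
      # both sexes come from the same study, so per-sex sample sizes are
      # strongly correlated: a common log-uniform base with mild jitter
      n_base <- rlogunif(1, n_range[1], n_range[2])
      n_m <- as.integer(min(n_range[2],
                            max(n_range[1],
                                round(n_base * exp(stats::rnorm(1, 0, 0.2))))))
      n_f <- as.integer(min(n_range[2],
                            max(n_range[1],
                                round(n_base * exp(stats::rnorm(1, 0, 0.2))))))

      draw <- function(mu, cv, n) {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      }
      xm <- draw(mu_m, cv_male, n_m)
      xf <- draw(mu_f, cv_female, n_f)

      sm <- summarise_chunk(xm); sf <- summarise_chunk(xf)
      trait_rows[[sp]] <- tibble::tibble(
        order = fam$order[i], family = fam$family[i], species = species,
        population = "pop_1", measure = measure, source = "synthetic",
        male_mean = unname(sm["mean"]), male_sd = unname(sm["sd"]),
        male_n = n_m,
        female_mean = unname(sf["mean"]), female_sd = unname(sf["sd"]),
        female_n = n_f
      )
      truth_rows[[sp]] <- tibble::tibble(
        order = fam$order[i], family = fam$family[i], species = species,
        true_class = cls, true_ratio = ratio,
        true_male_mean = mu_m, true_female_mean = mu_f,
        true_male_sd = mu_m * cv_male, true_female_sd = mu_f * cv_female,
        male_n = n_m, female_n = n_f
      )

      if (subgroup_split_prob > 0 && min(n_m, n_f) >= 4 &&
          stats::runif(1) < subgroup_split_prob) {
        for (sex in c("male", "female")) {
          v <- if (sex == "male") xm else xf
          k <- sample(2:min(3L, length(v) %/% 2L), 1)
          # contiguous chunks of size >= 2
          cuts <- sort(sample(seq(2, length(v) - 2), k - 1))
          grp <- findInterval(seq_along(v) - 1, cuts) + 1
          for (g in seq_len(k)) {
            sg <- summarise_chunk(v[grp == g])
            sub_rows[[length(sub_rows) + 1]] <- tibble::tibble(
              order = fam$order[i], family = fam$family[i],
              species = species, population = "pop_1",
              measure = measure, source = "synthetic",
              sex = sex, subgroup = sprintf("site_%d", g),
              mean = unname(sg["mean"]), sd = unname(sg["sd"]),
              n = as.integer(sg["n"])
            )
          }
        }
      }
    }
  }

  cfg <- list(n_orders = n_orders, families_per_order = families_per_order,
              richness_per_family = richness_per_family,
              sampled_fraction = sampled_fraction,
              true_class_probs = unname(true_class_probs),
              ratio_range_male = ratio_range_male,
              ratio_range_female = ratio_range_female,
              cv_male = cv_male, cv_female = cv_female, n_range = n_range,
              subgroup_split_prob = subgroup_split_prob,
              base_mass_range = base_mass_range, measure = measure,
              seed = seed)
  list(
    traits = dplyr::bind_rows(trait_rows),
    richness = fam[, c("order", "family", "species_count")],
    truth = dplyr::bind_rows(truth_rows),
    subgroups = if (length(sub_rows)) dplyr::bind_rows(sub_rows)
                else tibble::tibble(),
    config = cfg
  )
}

#' Write a simulated dataset to a directory
#'
#' Writes `traits.csv`, `richness.csv`, `truth.csv`, `subgroups.csv` (if
#' any) and a `meta.json` holding the generator configuration including
#' the seed.
#'
#' @param sim Output of [simulate_ssd_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$traits, file.path(dir, "traits.csv"), progress = FALSE)
  readr::write_csv(sim$richness, file.path(dir, "richness.csv"),
                   progress = FALSE)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  if (nrow(sim$subgroups) > 0) {
    readr::write_csv(sim$subgroups, file.path(dir, "subgroups.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(sim$config, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
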