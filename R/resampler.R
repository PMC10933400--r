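# Species-richness-weighted stratified resampling of classified species.
# Overrepresented taxa are down-weighted by sampling each stratum
# (family, or order for length data) a number of rows proportional to its
# species richness, many times, and tabulating class frequencies.

#' Resampling quota for a stratum
#'
#' The number of rows drawn from a stratum per repetition:
#' `fraction * richness`, rounded half away from zero (so a family of 10
#' species at 5% gets quota 1, and a family of 9 gets quota 0).
#'
#' @param richness Positive integer vector of species counts.
#' @param fraction Sampling fraction in (0, 1].
#' @return Integer vector of quotas.
#' @examples
#' compute_quota(c(9, 10, 51), 0.05)  # 0 1 3
#' @export
compute_quota <- function(richness, fraction) {
  stopifnot(fraction > 0, fraction <= 1, all(richness >= 1))
  as.integer(floor(richness * fraction + 0.5))
}

#' Richness-weighted rates of each dimorphism class
#'
#' Repeatedly draws, from each stratum, a quota of classified species
#' proportional to the stratum's species richness (without replacement),
#' and tabulates the frequency of each dimorphism class per mammalian
#' order and overall.  Strata are families by default; orders whose
#' families all fall below `min_stratum_species` species are pooled into a
#' single order-level stratum whose quota comes from the order's total
#' richness (so an order of several small families is still represented).
#' With `stratum_level = "order"` every order is one stratum (used for the
#' sparser body-length data at a lower fraction).
#'
#' If a stratum's quota exceeds its available classified rows, all
#' available rows are taken and a warning names the stratum.
#'
#' @param classified Output of [classify_dimorphism()]; one row per
#'   species.
#' @param richness Richness table (see [read_richness_table()]).
#' @param fraction Sampling fraction of each stratum's richness
#'   (0.05 for mass at family level; 0.01 for length at order level).
#' @param stratum_level `"family"` (default) or `"order"`.
#' @param reps Number of resampling repetitions (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param min_stratum_species Orders need at least this many species
#'   (by richness) to get their own row in the output, and families below
#'   it trigger the pooling rule; default 10.
#' @param pool_small_family_orders Pool orders whose families are all
#'   below `min_stratum_species` into one order-level stratum
#'   (default `TRUE`).
#' @return A tibble of class `ssd_rates` with one row per reported order
#'   plus `"overall"`: columns `stratum`, `rate_mono`, `rate_male`,
#'   `rate_female`, the across-repetition SDs `sd_mono`, `sd_male`,
#'   `sd_female`, and `reps_used`.  Rates within a row sum to 1.
#' @export
resample_rates <- function(classified, richness,
                           fraction = 0.05,
                           stratum_level = c("family", "order"),
                           reps = 1000, seed = NULL,
                           min_stratum_species = 10,
                           pool_small_family_orders = TRUE) {
  stratum_level <- match.arg(stratum_level)
  stopifnot(reps >= 1)
  richness <- validate_richness_table(richness)
  if (nrow(classified) == 0) stop("no classified species", call. = FALSE)

  orphans <- setdiff(unique(classified$family), richness$family)
  if (stratum_level == "family" && length(orphans) > 0) {
    stop("classified families absent from the richness table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  ord_rich <- richness |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(species_count = sum(.data$species_count),
                     .groups = "drop")
  orphan_ord <- setdiff(unique(classified$order), ord_rich$order)
  if (length(orphan_ord) > 0) {
    stop("classified orders absent from the richness table: ",
         paste(orphan_ord, collapse = ", "), call. = FALSE)
  }

  cls <- as.integer(factor(as.character(classified$class),
                           levels = .ssd_classes))
  if (anyNA(cls)) stop("unrecognised class labels", call. = FALSE)

  # ---- stratum construction ----------------------------------------------
  strata <- list()
  if (stratum_level == "family") {
    pooled_orders <- character(0)
    if (pool_small_family_orders) {
      small <- richness |>
        dplyr::group_by(.data$order) |>
        dplyr::summarise(
          all_small = all(.data$species_count < min_stratum_species),
          .groups = "drop")
      pooled_orders <- small$order[small$all_small]
    }
    for (o in pooled_orders) {
      q <- compute_quota(ord_rich$species_count[ord_rich$order == o], fraction)
      strata[[paste0("order:", o)]] <-
        list(rows = which(classified$order == o), quota = q)
    }
    fam <- richness[!(richness$order %in% pooled_orders), , drop = FALSE]
    for (i in seq_len(nrow(fam))) {
      q <- compute_quota(fam$species_count[i], fraction)
      if (q == 0) next
      strata[[paste0("family:", fam$family[i])]] <-
        list(rows = which(classified$family == fam$family[i]), quota = q)
    }
  } else {
    for (i in seq_len(nrow(ord_rich))) {
      q <- compute_quota(ord_rich$species_count[i], fraction)
      if (q == 0) next
      strata[[paste0("order:", ord_rich$order[i])]] <-
        list(rows = which(classified$order == ord_rich$order[i]), quota = q)
    }
  }
  strata <- Filter(function(s) s$quota > 0, strata)
  if (length(strata) == 0) {
    stop("every stratum has quota 0 at fraction ", fraction, call. = FALSE)
  }

  short <- vapply(strata, function(s) s$quota > length(s$rows), logical(1))
  if (any(short)) {
    warning("quota exceeds available classified rows; sampling all ",
            "available rows in: ",
            paste(names(strata)[short], collapse = ", "), call. = FALSE)
    for (nm in names(strata)[short]) {
      strata[[nm]]$quota <- length(strata[[nm]]$rows)
    }
    strata <- Filter(function(s) s$quota > 0, strata)
  }

  # ---- repetitions --------------------------------------------------------
  if (!is.null(seed)) set.seed(seed)
  orders <- sort(unique(classified$order))
  n_ord <- length(orders)
  ord_i <- match(classified$order, orders)
  n_take <- sum(vapply(strata, function(s) s$quota, integer(1)))

  overall_freq <- matrix(NA_real_, reps, 3)
  ord_counts <- array(0, dim = c(reps, n_ord, 3))
  for (r in seq_len(reps)) {
    take <- unlist(lapply(strata, function(s) {
      if (s$quota == length(s$rows)) s$rows
      else s$rows[sample.int(length(s$rows), s$quota)]
    }), use.names = FALSE)
    tab <- tabulate(ord_i[take] + n_ord * (cls[take] - 1L), nbins = 3L * n_ord)
    cmat <- matrix(tab, n_ord, 3)
    ord_counts[r, , ] <- cmat
    tot <- colSums(cmat)
    overall_freq[r, ] <- tot / sum(tot)
  }

  # per-order totals are fixed across repetitions (quotas are deterministic)
  mk_row <- function(stratum, freq) {
    keep <- stats::complete.cases(freq)
    tibble::tibble(
      stratum = stratum,
      rate_mono = mean(freq[keep, 1]),
      rate_male = mean(freq[keep, 2]),
      rate_female = mean(freq[keep, 3]),
      sd_mono = stats::sd(freq[keep, 1]),
      sd_male = stats::sd(freq[keep, 2]),
      sd_female = stats::sd(freq[keep, 3]),
      reps_used = sum(keep)
    )
  }

  rows <- list(mk_row("overall", overall_freq))
  report_orders <- ord_rich$order[ord_rich$species_count >=
                                    min_stratum_species]
  for (o in intersect(orders, report_orders)) {
    j <- match(o, orders)
    cnt <- ord_counts[, j, , drop = FALSE]
    dim(cnt) <- c(reps, 3)
    tot <- rowSums(cnt)
    freq <- cnt / ifelse(tot > 0, tot, NA_real_)
    if (all(tot == 0)) next
    rows[[length(rows) + 1]] <- mk_row(o, freq)
  }

  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("ssd_rates", class(out)),
            config = list(fraction = fraction, stratum_level = stratum_level,
                          reps = reps, seed = seed,
                          min_stratum_species = min_stratum_species,
                          pool_small_family_orders = pool_small_family_orders,
                          rows_per_rep = n_take))
}

#' Format and optionally write a rate table
#'
#' @param estimates An `ssd_rates` tibble from [resample_rates()].
#' @param path Optional CSV path to write the table to.
#' @param digits Rounding for the printed percentages (default 1).
#' @return A tibble with percentage-scale rates (invisibly if written).
#' @export
rate_report <- function(estimates, path = NULL, digits = 1) {
  stopifnot(nrow(estimates) > 0)
  out <- tibble::tibble(
    stratum = estimates$stratum,
    pct_monomorphic = round(100 * estimates$rate_mono, digits),
    pct_male_biased = round(100 * estimates$rate_male, digits),
    pct_female_biased = round(100 * estimates$rate_female, digits),
    reps_used = estimates$reps_used
  )
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
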