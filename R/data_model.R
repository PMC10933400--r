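# Core record model: one row per population, wide per sex.
# Canonical columns after normalization:
#   order, family, species, population, measure, source,
#   male_mean, male_sd, male_n, female_mean, female_sd, female_n

.trait_canonical <- c(
  "order", "family", "species", "population", "measure", "source",
  "male_mean", "male_sd", "male_n", "female_mean", "female_sd", "female_n"
)

.required_numeric <- c(
  "male_mean", "male_sd", "male_n",
  "female_mean", "female_sd", "female_n"
)

#' Convert a reported variance measure to a standard deviation
#'
#' Trait sources report within-sex spread as a standard deviation, a
#' standard error of the mean, or a 95% confidence-interval half-width.
#' All are normalized to the sample standard deviation:
#' SE gives `sd = se * sqrt(n)`; a 95% CI half-width gives
#' `sd = hw * sqrt(n) / qt(0.975, n - 1)`.
#'
#' @param value Numeric vector of reported variance measures (non-negative).
#' @param type Character vector, one of `"SD"`, `"SE"`, `"CI95"` per element
#'   (case-insensitive).
#' @param n Integer vector of per-sex sample sizes.
#' @return Numeric vector of standard deviations.
#' @examples
#' sd_from_variance(2, "SE", 25)    # 10
#' sd_from_variance(10, "SD", 25)   # 10
#' @export
sd_from_variance <- function(value, type, n) {
  type <- toupper(as.character(type))
  ok <- type %in% c("SD", "SE", "CI95")
  if (any(!ok)) {
    stop("unknown variance_type: ", paste(unique(type[!ok]), collapse = ", "),
         " (expected SD, SE or CI95)", call. = FALSE)
  }
  out <- value
  se_i <- type == "SE"
  ci_i <- type == "CI95"
  out[se_i] <- value[se_i] * sqrt(n[se_i])
  # CI half-width -> SE via the t quantile, then SE -> SD
  out[ci_i] <- value[ci_i] * sqrt(n[ci_i]) / stats::qt(0.975, n[ci_i] - 1)
  out
}

#' Read a comparative trait table
#'
#' Reads a CSV with one row per population and per-sex summary statistics,
#' and normalizes it to the canonical record layout.  Variance measures may
#' be given directly as standard deviations (`male_sd`, `female_sd`) or as
#' generic columns (`male_var`, `female_var`) tagged by a per-row
#' `variance_type` column (`SD`, `SE` or `CI95`); the latter are converted
#' with [sd_from_variance()].
#'
#' Rows missing a required field, or with non-positive means, negative SDs
#' or sample sizes below 1, are rejected; the rejected rows and reasons are
#' attached as the `"rejected"` attribute and reported via a message.
#'
#' @param path Path to the CSV file.
#' @param measure Optional, `"mass"` or `"length"`: keep only records of
#'   this measure (a missing `measure` column is filled with this value).
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(order = "Order", male_mean = "M_mean")`.
#' @return A tibble of population records in canonical layout, with
#'   attribute `"rejected"` (a tibble with columns `row` and `reason`).
#' @export
read_trait_table <- function(path, measure = NULL, dialect = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, guess_max = 100000)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed CSV in ", path, ": first problem at data row ",
         probs$row[1], " (", probs$expected[1], " / actual ",
         probs$actual[1], ")", call. = FALSE)
  }
  if (!is.null(dialect)) {
    miss <- setdiff(unname(dialect), names(raw))
    if (length(miss) > 0) {
      stop("dialect names columns absent from the file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    names(raw)[match(unname(dialect), names(raw))] <- names(dialect)
  }
  normalize_trait_table(raw, measure = measure)
}

#' @rdname read_trait_table
#' @param x A data frame already loaded, in the same layout the reader
#'   accepts.
#' @export
normalize_trait_table <- function(x, measure = NULL) {
  x <- tibble::as_tibble(x)
  if (!"population" %in% names(x)) x$population <- ""
  if (!"source" %in% names(x)) x$source <- ""
  for (col in c("order", "family", "species", "population", "source")) {
    if (col %in% names(x)) {
      x[[col]] <- as.character(x[[col]])
      if (col %in% c("population", "source")) {
        x[[col]][is.na(x[[col]])] <- ""
      }
    }
  }
  if (!"measure" %in% names(x)) {
    x$measure <- if (is.null(measure)) "mass" else measure
  }

  # variance normalization
  has_sd <- all(c("male_sd", "female_sd") %in% names(x))
  has_var <- all(c("male_var", "female_var", "variance_type") %in% names(x))
  if (!has_sd && !has_var) {
    stop("no variance columns found: need male_sd/female_sd or ",
         "male_var/female_var + variance_type", call. = FALSE)
  }
  if (!has_sd) {
    x$male_sd <- sd_from_variance(x$male_var, x$variance_type, x$male_n)
    x$female_sd <- sd_from_variance(x$female_var, x$variance_type, x$female_n)
  }

  core <- intersect(.trait_canonical, names(x))
  miss <- setdiff(c("order", "family", "species", .required_numeric), core)
  if (length(miss) > 0) {
    stop("trait table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  reasons <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  num <- function(col) suppressWarnings(as.numeric(x[[col]]))
  for (col in .required_numeric) {
    flag(!is.finite(num(col)), paste0("missing or non-numeric ", col))
  }
  flag(num("male_mean") <= 0 | num("female_mean") <= 0, "non-positive mean")
  flag(num("male_sd") < 0 | num("female_sd") < 0, "negative sd")
  flag(num("male_n") < 1 | num("female_n") < 1, "sample size below 1")
  flag(is.na(x$species) | x$species == "", "missing species")
  flag(is.na(x$order) | x$order == "" | is.na(x$family) | x$family == "",
       "missing taxonomy")

  rejected <- tibble::tibble(row = which(!is.na(reasons)),
                             reason = reasons[!is.na(reasons)])
  keep <- x[is.na(reasons), , drop = FALSE]
  for (col in .required_numeric) keep[[col]] <- as.numeric(keep[[col]])
  keep$male_n <- as.integer(round(keep$male_n))
  keep$female_n <- as.integer(round(keep$female_n))

  extra <- setdiff(names(keep), .trait_canonical)
  extra <- setdiff(extra, c("male_var", "female_var", "variance_type"))
  out <- keep[, c(.trait_canonical, extra), drop = FALSE]
  if (!is.null(measure)) out <- out[out$measure == measure, , drop = FALSE]

  chk <- .check_family_order(out)
  if (!is.null(chk)) stop(chk, call. = FALSE)

  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  attr(out, "rejected") <- rejected
  out
}

.check_family_order <- function(x) {
  map <- unique(x[, c("order", "family")])
  dup <- map$family[duplicated(map$family)]
  if (length(dup) > 0) {
    return(paste0("family mapped to more than one order: ",
                  paste(unique(dup), collapse = ", ")))
  }
  NULL
}

#' Write a canonical trait table
#'
#' @param records Tibble of population records (canonical layout).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a species-richness table
#'
#' Maps each family to its parent order and its extant species count; the
#' counts are the stratified-resampling weights.
#'
#' @param path Path to a CSV with columns `order`, `family`,
#'   `species_count` (a `dialect` mapping may rename them as in
#'   [read_trait_table()]).
#' @inheritParams read_trait_table
#' @return A tibble with columns `order`, `family`, `species_count`.
#' @export
read_richness_table <- function(path, dialect = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    names(x)[match(unname(dialect), names(x))] <- names(dialect)
  }
  validate_richness_table(x)
}

#' @rdname read_richness_table
#' @param x A data frame with columns `order`, `family`, `species_count`.
#' @export
validate_richness_table <- function(x) {
  x <- tibble::as_tibble(x)
  miss <- setdiff(c("order", "family", "species_count"), names(x))
  if (length(miss) > 0) {
    stop("richness table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$family)) {
    stop("richness table lists a family more than once: ",
         paste(unique(x$family[duplicated(x$family)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$species_count) | x$species_count < 1)) {
    stop("species_count must be >= 1 for every family", call. = FALSE)
  }
  x$species_count <- as.integer(round(x$species_count))
  x[, c("order", "family", "species_count")]
}

#' Keep the best-sampled population per species
#'
#' When several populations (or subspecies) of one species are available,
#' retains the one with the highest sample size.  "Highest" is taken as the
#' larger per-record minimum of the two per-sex sample sizes (the binding
#' constraint on CI width), with ties broken by the summed sample size and
#' then by input order.
#'
#' @param records Tibble of population records, one measure.
#' @return Tibble with exactly one row per species.
#' @export
select_best_population <- function(records) {
  if (nrow(records) == 0) return(records)
  att <- attributes(records)
  out <- records |>
    dplyr::mutate(
      .row = dplyr::row_number(),
      .min_n = pmin(.data$male_n, .data$female_n),
      .tot_n = .data$male_n + .data$female_n
    ) |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(dplyr::desc(.data$.min_n), dplyr::desc(.data$.tot_n),
                   .data$.row, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -".min_n", -".tot_n")
  out
}

#' Filter records by a per-sex minimum sample size
#'
#' Keeps records where both sexes reach `n_min` individuals; small samples
#' inflate the CI of the sex difference and bias classification towards
#' monomorphism.
#'
#' @param records Tibble of population records.
#' @param n_min Positive integer minimum per-sex sample size.
#' @return Filtered tibble; the number of removed rows is attached as
#'   attribute `"n_removed"` and reported via a message.
#' @export
filter_min_n <- function(records, n_min) {
  stopifnot(is.numeric(n_min), length(n_min) == 1, n_min >= 1)
  keep <- records$male_n >= n_min & records$female_n >= n_min
  out <- records[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " record(s) removed by the minimum sample size n >= ",
            n_min)
  }
  attr(out, "n_removed") <- n_removed
  out
}
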