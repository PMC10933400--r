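# CI of the between-sex difference in means from summary statistics, and
# the monomorphic / male-biased / female-biased classification.

.ssd_classes <- c("monomorphic", "male_biased", "female_biased")

#' Confidence interval of the between-sex difference in means
#'
#' Computes `diff = male_mean - female_mean` and its two-sided
#' `(1 - alpha)` confidence interval from per-sex summary statistics.  The
#' default `"welch_t"` method uses the unpooled standard error
#' `se = sqrt(sd_m^2/n_m + sd_f^2/n_f)` with Welch–Satterthwaite degrees
#' of freedom; `"normal_z"` uses the standard normal quantile.  An
#' unpooled interval is used because male and female spreads are generally
#' unequal in body-size data.
#'
#' All arguments are vectorized over species.
#'
#' @param male_mean,male_sd,male_n Male summary statistics.
#' @param female_mean,female_sd,female_n Female summary statistics.
#' @param alpha Two-sided error rate in (0, 1); default 0.05.
#' @param method `"welch_t"` (default) or `"normal_z"`.
#' @return A tibble with columns `diff`, `se`, `df` (`Inf` for
#'   `"normal_z"`), `lo`, `hi`, `alpha`, `method` and `degenerate`
#'   (`TRUE` where both SDs are zero, giving a width-0 interval).
#' @examples
#' difference_ci(100, 10, 25, 90, 10, 25)
#' @export
difference_ci <- function(male_mean, male_sd, male_n,
                          female_mean, female_sd, female_n,
                          alpha = 0.05, method = c("welch_t", "normal_z")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  if (any(male_n < 2 | female_n < 2)) {
    stop("difference_ci needs n >= 2 for both sexes", call. = FALSE)
  }
  if (any(male_sd < 0 | female_sd < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  vm <- male_sd^2 / male_n
  vf <- female_sd^2 / female_n
  se <- sqrt(vm + vf)
  degenerate <- se == 0
  if (method == "welch_t") {
    df <- se^4 / (vm^2 / (male_n - 1) + vf^2 / (female_n - 1))
    df[degenerate] <- NA_real_
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    df <- rep(Inf, length(se))
    q <- stats::qnorm(1 - alpha / 2)
  }
  hw <- q * se
  hw[degenerate] <- 0
  d <- male_mean - female_mean
  tibble::tibble(diff = d, se = se, df = df,
                 lo = d - hw, hi = d + hw,
                 alpha = alpha, method = method, degenerate = degenerate)
}

#' Classify species by the sign of the sex-difference CI
#'
#' Assigns each record a dimorphism class from the confidence interval of
#' `male_mean - female_mean`: `monomorphic` when the interval straddles
#' zero, `male_biased` when it lies entirely above zero, `female_biased`
#' when entirely below.  This is decision-equivalent to a two-sided Welch
#' two-sample t-test at level `alpha`.
#'
#' @param records Tibble of population records (canonical layout,
#'   both sexes with `n >= 2`).
#' @inheritParams difference_ci
#' @return `records` with added columns `diff`, `ci_lo`, `ci_hi`, `class`
#'   (factor with levels monomorphic, male_biased, female_biased), `ratio`
#'   (larger-sex mean over smaller-sex mean, `>= 1`) and
#'   `proportional_diff` (`(male - female) / male`, the share of male mass
#'   by which the sexes differ).
#' @export
classify_dimorphism <- function(records, alpha = 0.05,
                                method = c("welch_t", "normal_z")) {
  method <- match.arg(method)
  ci <- difference_ci(records$male_mean, records$male_sd, records$male_n,
                      records$female_mean, records$female_sd,
                      records$female_n, alpha = alpha, method = method)
  cls <- ifelse(ci$lo > 0, "male_biased",
                ifelse(ci$hi < 0, "female_biased", "monomorphic"))
  out <- records
  out$diff <- ci$diff
  out$ci_lo <- ci$lo
  out$ci_hi <- ci$hi
  out$class <- factor(cls, levels = .ssd_classes)
  out$ratio <- pmax(records$male_mean, records$female_mean) /
    pmin(records$male_mean, records$female_mean)
  out$proportional_diff <- (records$male_mean - records$female_mean) /
    records$male_mean
  attr(out, "alpha") <- alpha
  attr(out, "ci_method") <- method
  out
}

#' Summarise dimorphism ratios by class
#'
#' For male-biased species the ratio is male/female mean mass; for
#' female-biased species it is female/male.  Reports the per-class mean
#' ratio, the count, and the most extreme species in each direction.
#' Classes with no members are omitted (with a message).
#'
#' @param classified Output of [classify_dimorphism()].
#' @return A tibble with columns `class`, `n`, `mean_ratio`, `max_ratio`,
#'   `max_species`.
#' @export
ratio_summary <- function(classified) {
  if (nrow(classified) == 0) stop("no classified species", call. = FALSE)
  dimorphic <- classified[classified$class %in%
                            c("male_biased", "female_biased"), ,
                          drop = FALSE]
  if (nrow(dimorphic) == 0) {
    message("no species in class(es): male_biased, female_biased")
    return(tibble::tibble(class = character(0), n = integer(0),
                          mean_ratio = numeric(0), max_ratio = numeric(0),
                          max_species = character(0)))
  }
  out <- dimorphic |>
    dplyr::group_by(class = as.character(.data$class)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      max_ratio = max(.data$ratio),
      max_species = .data$species[which.max(.data$ratio)],
      .groups = "drop"
    )
  absent <- setdiff(c("male_biased", "female_biased"), out$class)
  if (length(absent) > 0) {
    message("no species in class(es): ", paste(absent, collapse = ", "))
  }
  out
}
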