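# Exact combined-sample moments for subgroup summaries reported
# separately by season or site.

#' Pool subgroup summaries into combined-sample moments
#'
#' Combines per-subgroup means, standard deviations and sample sizes for
#' one population and sex into the exact moments of the concatenated
#' sample:
#' \deqn{N = \sum n_i, \quad \bar{x} = \sum n_i \bar{x}_i / N,}
#' \deqn{s^2 = \frac{\sum (n_i - 1) s_i^2 + \sum n_i (\bar{x}_i - \bar{x})^2}{N - 1}.}
#' For any partition of a raw sample into subgroups this reproduces the
#' full-sample mean and sample variance exactly.  Subgroups with
#' \eqn{n_i = 1} carry no within-group sum of squares; their `sd` may be
#' `NA` or 0.
#'
#' @param mean Numeric vector of subgroup means (same measure and units).
#' @param sd Numeric vector of subgroup standard deviations (`NA` allowed
#'   where `n == 1`).
#' @param n Integer vector of subgroup sample sizes (all `>= 1`).
#' @param denominator `"unbiased"` (default) divides the combined sum of
#'   squares by `N - 1`; `"population"` divides by `N`.
#' @return A list with elements `mean`, `sd`, `n`.
#' @examples
#' pool_subgroups(mean = c(1, 3), sd = c(0, 0), n = c(2, 2))
#' @export
pool_subgroups <- function(mean, sd, n,
                           denominator = c("unbiased", "population")) {
  denominator <- match.arg(denominator)
  k <- length(mean)
  if (k == 0) stop("at least one subgroup is required", call. = FALSE)
  if (length(sd) != k || length(n) != k) {
    stop("mean, sd and n must have the same length", call. = FALSE)
  }
  if (any(!is.finite(n) | n < 1)) {
    stop("every subgroup must have n >= 1", call. = FALSE)
  }
  sd <- ifelse(is.na(sd) & n == 1, 0, sd)
  if (any(!is.finite(sd) | sd < 0)) {
    stop("every subgroup with n >= 2 must have a non-negative sd",
         call. = FALSE)
  }
  if (k == 1) {
    return(list(mean = mean[1], sd = sd[1], n = as.integer(n[1])))
  }
  N <- sum(n)
  m <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2) + sum(n * (mean - m)^2)
  denom <- if (denominator == "unbiased") N - 1 else N
  list(mean = m, sd = sqrt(ss / denom), n = as.integer(N))
}

#' Pool subgroup rows of a long-format trait table
#'
#' Applies [pool_subgroups()] within groups of a long table where each row
#' is one subgroup of one (species, population, sex) combination.
#'
#' @param x A data frame with columns `mean`, `sd`, `n` plus the grouping
#'   columns.
#' @param group_cols Character vector of grouping columns; defaults to all
#'   columns of `x` except `mean`, `sd`, `n` and any `subgroup` label.
#' @inheritParams pool_subgroups
#' @return A tibble with one pooled row per group.
#' @export
pool_trait_subgroups <- function(x, group_cols = NULL,
                                 denominator = c("unbiased", "population")) {
  denominator <- match.arg(denominator)
  x <- tibble::as_tibble(x)
  stopifnot(all(c("mean", "sd", "n") %in% names(x)))
  if (is.null(group_cols)) {
    group_cols <- setdiff(names(x), c("mean", "sd", "n", "subgroup"))
  }
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      {
        p <- pool_subgroups(.data$mean, .data$sd, .data$n,
                            denominator = denominator)
        tibble::tibble(mean = p$mean, sd = p$sd, n = p$n)
      },
      .groups = "drop"
    )
}
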