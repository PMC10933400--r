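# Paired Wilcoxon signed-rank comparisons of male vs female standard
# deviations.  Implemented from the rank statistic directly so that the
# exact conditional distribution is available also under ties (the exact
# branch enumerates the +/- sign distribution over midranks by
# convolution); the normal branch applies the usual tie and continuity
# corrections and agrees with stats::wilcox.test.

#' Paired Wilcoxon signed-rank test
#'
#' Tests symmetry of paired differences about zero.  Zero differences are
#' dropped; ties among absolute differences receive midranks.  `V` is the
#' sum of the ranks of the positive differences.  Mode `"exact"`
#' enumerates the conditional distribution of `V` given the observed
#' ranks (valid under ties); `"normal_approx"` uses the normal
#' approximation with tie and continuity corrections; `"auto"` (default)
#' is exact for up to 25 non-zero differences.
#'
#' @param x Numeric vector: first member of each pair, or the differences
#'   themselves if `y` is `NULL`.
#' @param y Optional numeric vector paired with `x`.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A list with `V`, `p` (two-sided), `n_effective` (non-zero
#'   differences) and `mode_used`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # V = 6, p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate sample: all paired differences are zero",
                   call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 25) "exact" else "normal_approx"

  if (mode == "exact") {
    p <- .signed_rank_exact_p(r, V)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)   # equals the tie-corrected variance
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  list(V = V, p = p, n_effective = n, mode_used = mode)
}

# Exact two-sided p for the signed-rank statistic given midranks r.
# Doubling the ranks makes them integers; the distribution of 2V over the
# 2^n equiprobable sign assignments is built by convolution.
.signed_rank_exact_p <- function(r, V) {
  s <- as.integer(round(2 * r))
  S <- sum(s)
  g <- numeric(S + 1)
  g[1] <- 1
  for (si in s) {
    shifted <- c(numeric(si), g[seq_len(S + 1 - si)])
    g <- g + shifted
  }
  tot <- 2^length(s)
  v2 <- as.integer(round(2 * V))
  p_le <- sum(g[seq_len(v2 + 1)]) / tot
  p_ge <- sum(g[seq.int(v2 + 1, S + 1)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Per-class comparison of male and female standard deviations
#'
#' Summarises the per-species within-sex standard deviations for all
#' species and within each dimorphism class, and runs a paired Wilcoxon
#' signed-rank test of male vs female SD per group.  Groups with fewer
#' than two species, or with all differences zero, are reported without a
#' test and flagged in `note`.
#'
#' @param classified Output of [classify_dimorphism()].
#' @param mode Test mode passed to [wilcoxon_signed_rank()].
#' @return A tibble with one row per group (`all` plus each class):
#'   per-sex mean and median SD, `V`, `p`, `n_species` and `note`.
#' @export
sd_summary <- function(classified, mode = "auto") {
  if (nrow(classified) == 0) stop("no classified species", call. = FALSE)
  groups <- c(list(all = classified),
              split(classified, classified$class))
  rows <- lapply(names(groups), function(lbl) {
    g <- groups[[lbl]]
    row <- tibble::tibble(
      group = lbl, n_species = nrow(g),
      mean_sd_male = if (nrow(g)) mean(g$male_sd) else NA_real_,
      mean_sd_female = if (nrow(g)) mean(g$female_sd) else NA_real_,
      median_sd_male = if (nrow(g)) stats::median(g$male_sd) else NA_real_,
      median_sd_female = if (nrow(g)) stats::median(g$female_sd) else NA_real_,
      V = NA_real_, p = NA_real_, note = ""
    )
    if (nrow(g) < 2) {
      row$note <- "test skipped: fewer than 2 species"
    } else if (all(g$male_sd == g$female_sd)) {
      row$note <- "test skipped: degenerate (all differences zero)"
    } else {
      w <- wilcoxon_signed_rank(g$male_sd, g$female_sd, mode = mode)
      row$V <- w$V
      row$p <- w$p
    }
    row
  })
  dplyr::bind_rows(rows)
}
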