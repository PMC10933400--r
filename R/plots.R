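# Diagnostic plots: the cutoff fit and the rate estimates.

#' Plot an elbow fit
#'
#' Points, the fitted exponential decay and a vertical marker at the
#' elbow.
#'
#' @param fit An `ssd_elbow` object from [fit_decay_elbow()].
#' @return A ggplot object.
#' @export
plot_cutoff_fit <- function(fit) {
  stopifnot(inherits(fit, "ssd_elbow"))
  grid <- tibble::tibble(
    n = seq(min(fit$data$n), max(fit$data$n), length.out = 200))
  grid$y <- fit$a * exp(-fit$b * grid$n) + fit$c
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$n, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = fit$elbow_x, linetype = "dashed") +
    ggplot2::labs(x = "per-sex sample size",
                  y = "proportional mass difference",
                  title = sprintf("Elbow at n = %.2f", fit$elbow_x)) +
    ggplot2::theme_minimal()
}

#' Plot rate estimates as stacked bars
#'
#' One stacked bar per stratum (orders plus overall) showing the three
#' class rates.
#'
#' @param estimates An `ssd_rates` tibble from [resample_rates()].
#' @return A ggplot object.
#' @export
plot_rate_estimates <- function(estimates) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(estimates)[, c("stratum", "rate_mono", "rate_male",
                                     "rate_female")],
    cols = -"stratum", names_to = "class", values_to = "rate")
  long$class <- factor(long$class,
                       levels = c("rate_female", "rate_mono", "rate_male"),
                       labels = c("female-biased", "monomorphic",
                                  "male-biased"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$rate,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c("female-biased" = "#7b3294",
                                          "monomorphic" = "#bababa",
                                          "male-biased" = "#008837")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "richness-weighted rate", fill = NULL) +
    ggplot2::theme_minimal()
}
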