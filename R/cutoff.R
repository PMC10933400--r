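# Minimum per-sex sample size from the elbow of the exponential decay of
# proportional mass difference against sample size.

#' Per-sex points for the sample-size cutoff fit
#'
#' For one sex, the proportional mass difference
#' `|male_mean - female_mean| / mean(sex)` is plotted against that sex's
#' sample size; at low n sampling error inflates the apparent difference,
#' decaying roughly exponentially towards the dataset's baseline level of
#' dimorphism as n grows.
#'
#' @param records Tibble of population records.
#' @param sex `"male"` or `"female"`: whose sample size (and mean, as the
#'   denominator) to use.
#' @return A tibble with columns `n` and `y`.
#' @export
cutoff_points <- function(records, sex = c("male", "female")) {
  sex <- match.arg(sex)
  denom <- records[[paste0(sex, "_mean")]]
  tibble::tibble(
    n = records[[paste0(sex, "_n")]],
    y = abs(records$male_mean - records$female_mean) / denom
  )
}

#' Fit an exponential decay and locate its elbow
#'
#' Fits `y = a * exp(-b * x) + c` (with `b > 0`) by nonlinear least
#' squares and returns the elbow of the fitted curve.  The default
#' `"first_derivative_fraction"` rule returns the x at which the absolute
#' slope of the fitted curve has fallen to `slope_fraction` of its maximum
#' over the observed range, i.e. `x = x_min + log(1/slope_fraction) / b`;
#' `"max_curvature"` returns the curvature-maximizing x.
#'
#' @param n Numeric vector of sample sizes (x values).
#' @param y Numeric vector of proportional differences (same length).
#' @param method `"first_derivative_fraction"` (default, with
#'   `slope_fraction = 0.5`, the conventional knee rule) or
#'   `"max_curvature"`.
#' @param slope_fraction Fraction of the maximum absolute slope, in (0, 1).
#' @return An object of class `ssd_elbow`: a list with `a`, `b`, `c`,
#'   `elbow_x`, `method`, `slope_fraction` and the fitted `data`.
#' @examples
#' x <- seq(0, 10, by = 0.25)
#' fit_decay_elbow(x, exp(-x))$elbow_x  # log(2)
#' @export
fit_decay_elbow <- function(n, y,
                            method = c("first_derivative_fraction",
                                       "max_curvature"),
                            slope_fraction = 0.5) {
  method <- match.arg(method)
  stopifnot(length(n) == length(y), slope_fraction > 0, slope_fraction < 1)
  ok <- is.finite(n) & is.finite(y)
  n <- as.numeric(n[ok]); y <- as.numeric(y[ok])
  if (length(n) < 5 || length(unique(n)) < 3) {
    stop("need at least 5 points spanning at least 3 distinct n values",
         call. = FALSE)
  }
  x_min <- min(n); x_max <- max(n)

  # Separable least squares: for fixed b the model is linear in (a, c),
  # so profile the residual sum of squares over b (variable projection),
  # then polish all three parameters with Levenberg-Marquardt.
  prof <- function(b) {
    z <- exp(-b * (n - x_min))
    f <- stats::lm.fit(cbind(1, z), y)
    list(rss = sum(f$residuals^2), c = f$coefficients[1],
         a = f$coefficients[2])
  }
  b_grid <- exp(seq(log(0.05 / (x_max - x_min)), log(50 / (x_max - x_min)),
                    length.out = 60))
  rss <- vapply(b_grid, function(b) prof(b)$rss, numeric(1))
  i <- which.min(rss)
  b0 <- stats::optimize(function(b) prof(b)$rss,
                        interval = c(b_grid[max(1, i - 1)],
                                     b_grid[min(length(b_grid), i + 1)]),
                        tol = 1e-10)$minimum
  p0 <- prof(b0)
  if (!is.finite(p0$a) || p0$a <= 1e-10 * max(abs(y), 1e-300)) {
    stop("no decaying exponential fits these points (fitted amplitude ",
         "is not positive); supply a cutoff directly instead", call. = FALSE)
  }
  a <- unname(p0$a) * exp(b0 * x_min)  # back to the unshifted form
  b <- b0; cc <- unname(p0$c)

  polish <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-b * n) + c,
      data = data.frame(n = n, y = y),
      start = list(a = a, b = b, c = cc),
      lower = c(a = 0, b = 1e-10, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    if (is.finite(cf["b"]) && cf["b"] > 0 &&
        sum(stats::resid(polish)^2) <= prof(unname(cf["b"]))$rss + 1e-12) {
      a <- unname(cf["a"]); b <- unname(cf["b"]); cc <- unname(cf["c"])
    }
  }
  if (!is.finite(b) || b <= 0) {
    stop("fitted decay rate is not positive; supply a cutoff directly",
         call. = FALSE)
  }

  elbow_x <- if (method == "first_derivative_fraction") {
    # |dy/dx| = a b exp(-b x) is maximal at x_min over the observed range
    x_min + log(1 / slope_fraction) / b
  } else {
    curv <- function(x) {
      d1 <- -a * b * exp(-b * x)
      d2 <- a * b^2 * exp(-b * x)
      abs(d2) / (1 + d1^2)^1.5
    }
    stats::optimize(curv, interval = c(x_min, x_max), maximum = TRUE)$maximum
  }
  if (elbow_x > x_max) {
    stop("elbow (", signif(elbow_x, 4), ") lies beyond the observed n ",
         "range; the fit is too flat to locate a knee - supply a cutoff ",
         "directly instead", call. = FALSE)
  }

  structure(
    list(a = a, b = b, c = cc, elbow_x = elbow_x, method = method,
         slope_fraction = slope_fraction,
         data = tibble::tibble(n = n, y = y)),
    class = "ssd_elbow"
  )
}

#' @export
print.ssd_elbow <- function(x, ...) {
  cat("Exponential-decay elbow fit\n")
  cat(sprintf("  y = %.4g * exp(-%.4g * x) + %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  elbow at x = %.3f (%s", x$elbow_x, x$method))
  if (x$method == "first_derivative_fraction") {
    cat(sprintf(", slope fraction %.2f", x$slope_fraction))
  }
  cat(")\n")
  invisible(x)
}

#' Choose the minimum per-sex sample size from per-sex elbows
#'
#' The binding constraint is the larger of the two per-sex elbows; the
#' cutoff is its floor (e.g. elbows 9.88 and 9.16 give a minimum sample
#' size of 9 for each sex).
#'
#' @param elbow_male,elbow_female Per-sex elbows: `ssd_elbow` objects or
#'   plain numbers.
#' @return Integer minimum per-sex sample size.
#' @examples
#' choose_min_n(9.88, 9.16)  # 9
#' @export
choose_min_n <- function(elbow_male, elbow_female) {
  val <- function(e) if (inherits(e, "ssd_elbow")) e$elbow_x else as.numeric(e)
  as.integer(floor(max(val(elbow_male), val(elbow_female))))
}
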