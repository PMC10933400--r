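# Shared fixtures and independent oracles.

# A raw sample of size n with exactly the requested sample mean and SD
# (rescaled ranks), so t.test() on it is a Welch test from those summaries.
exact_moment_sample <- function(mean, sd, n) {
  z <- as.numeric(scale(seq_len(n)))
  mean + sd * z
}

# Independent dimorphism decision: Welch two-sample t-test on raw samples
# reconstructed from the summaries.
welch_oracle_dimorphic <- function(mm, ms, mn, fm, fs, fn, alpha = 0.05) {
  x <- exact_moment_sample(mm, ms, mn)
  y <- exact_moment_sample(fm, fs, fn)
  stats::t.test(x, y, var.equal = FALSE)$p.value < alpha
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (midranks, zeros assumed already removed).
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(V_all <= V_obs), mean(V_all >= V_obs)))
}

# Minimal canonical population record table.
make_records <- function(n_rows = 1, ...) {
  defaults <- tibble::tibble(
    order = "Order_A", family = "Fam_A",
    species = sprintf("Sp %03d", seq_len(n_rows)),
    population = "", measure = "mass", source = "",
    male_mean = 100, male_sd = 10, male_n = 25L,
    female_mean = 90, female_sd = 10, female_n = 25L
  )
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}
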