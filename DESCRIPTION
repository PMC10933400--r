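Package: ssdrates
Title: Statistical Classification and Richness-Weighted Rates of Sexual
    Size Dimorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates rates of sexual size dimorphism across a taxonomy
    from sex-segregated summary statistics (per-sex mean, standard
    deviation and sample size of body mass or length).  Species are
    classified as monomorphic, male-biased or female-biased dimorphic from
    the 95% confidence interval of the between-sex difference in means
    (Welch or normal method); class rates per order and overall are then
    estimated by species-richness-weighted stratified resampling at the
    family or order level.  Supporting tools cover pooling of per-season
    or per-site subgroup summaries into exact combined-sample moments, an
    elbow rule on the exponential decay of proportional mass difference
    with sample size to choose a minimum per-sex sample size, paired
    Wilcoxon signed-rank comparisons of male and female standard
    deviations, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
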