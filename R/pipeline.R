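# End-to-end orchestration: ingest -> pool -> cutoff -> filter -> select
# -> classify -> resample -> SD tests -> report, with a run manifest.

.pipeline_defaults <- list(
  measure = "mass",
  alpha = 0.05,
  ci_method = "welch_t",
  min_n = "auto",
  cutoff = list(method = "first_derivative_fraction", slope_fraction = 0.5,
                fallback_n = NULL),
  resample = list(fraction = 0.05, stratum_level = "family", reps = 1000,
                  seed = NULL, min_stratum_species = 10,
                  pool_small_family_orders = TRUE),
  write_plots = FALSE
)

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full dimorphism-rate pipeline
#'
#' Orchestrates the analysis end to end: read (or simulate) the trait and
#' richness tables, pool any subgroup rows, fit the per-sex sample-size
#' elbow, filter by the resulting minimum n, keep the best-sampled
#' population per species, classify each species from the CI of the sex
#' difference, estimate richness-weighted class rates, and compare male
#' and female SDs.  All randomness flows through `resample$seed`, so a
#' rerun with the same configuration and inputs is bit-identical.
#'
#' @param config A configuration list or path to a YAML file.  Keys (all
#'   optional except the data source): `measure`, `alpha`, `ci_method`,
#'   `min_n` (`"auto"` to use the elbow rule, or an integer), `cutoff`
#'   (`method`, `slope_fraction`, `fallback_n` used if the elbow fit
#'   fails), `resample` (`fraction`, `stratum_level`, `reps`, `seed`,
#'   `min_stratum_species`, `pool_small_family_orders`), `write_plots`,
#'   and either `input` (paths `traits`, `richness`, optional
#'   `subgroups`) or `simulate` (arguments to [simulate_ssd_data()]).
#' @param out_dir Optional output directory; if given, writes
#'   `classified.csv`, `rates.csv`, `sd_summary.csv`, `ratio_summary.csv`,
#'   `manifest.json` and (if `write_plots`) diagnostic plots.
#' @return Invisibly, a list with `records`, `elbows`, `min_n`,
#'   `classified`, `rates`, `ratios`, `sd_tests` and `manifest`.
#' @export
run_ssd_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.pipeline_defaults, config)
  digests <- list()

  # ---- ingest -------------------------------------------------------------
  subgroups <- NULL
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate",
                  do.call(simulate_ssd_data, cfg$simulate))
    records <- sim$traits
    richness <- sim$richness
    truth <- sim$truth
    if (nrow(sim$subgroups) > 0) subgroups <- sim$subgroups
  } else if (!is.null(cfg$input)) {
    records <- .stage("read_traits",
                      read_trait_table(cfg$input$traits,
                                       measure = cfg$measure,
                                       dialect = cfg$input$trait_dialect))
    richness <- .stage("read_richness",
                       read_richness_table(cfg$input$richness))
    digests <- lapply(
      c(traits = cfg$input$traits, richness = cfg$input$richness),
      function(p) unname(tools::md5sum(p)))
    if (!is.null(cfg$input$subgroups)) {
      subgroups <- readr::read_csv(cfg$input$subgroups,
                                   show_col_types = FALSE, progress = FALSE)
    }
  } else {
    stop("config needs either 'input' or 'simulate'", call. = FALSE)
  }
  n_ingested <- nrow(records)

  # ---- pool subgroup rows into wide records -------------------------------
  if (!is.null(subgroups) && nrow(subgroups) > 0) {
    pooled <- .stage("pool", {
      long <- pool_trait_subgroups(subgroups)
      wide <- tidyr::pivot_wider(
        long,
        names_from = "sex", values_from = c("mean", "sd", "n"),
        names_glue = "{sex}_{.value}")
      wide[, intersect(.trait_canonical, names(wide)), drop = FALSE]
    })
    key <- function(d) paste(d$species, d$population)
    replaced <- key(records) %in% key(pooled)
    pooled$male_n <- as.integer(pooled$male_n)
    pooled$female_n <- as.integer(pooled$female_n)
    records <- dplyr::bind_rows(records[!replaced, , drop = FALSE],
                                dplyr::mutate(pooled,
                                              measure = cfg$measure))
  }

  # ---- sample-size cutoff -------------------------------------------------
  elbows <- NULL
  if (identical(cfg$min_n, "auto")) {
    elbows <- .stage("cutoff", tryCatch({
      list(
        male = fit_decay_elbow(cutoff_points(records, "male")$n,
                               cutoff_points(records, "male")$y,
                               method = cfg$cutoff$method,
                               slope_fraction = cfg$cutoff$slope_fraction),
        female = fit_decay_elbow(cutoff_points(records, "female")$n,
                                 cutoff_points(records, "female")$y,
                                 method = cfg$cutoff$method,
                                 slope_fraction = cfg$cutoff$slope_fraction))
    }, error = function(e) {
      if (is.null(cfg$cutoff$fallback_n)) stop(e)
      warning("elbow fit failed (", conditionMessage(e),
              "); using fallback_n = ", cfg$cutoff$fallback_n, call. = FALSE)
      NULL
    }))
    min_n <- if (is.null(elbows)) as.integer(cfg$cutoff$fallback_n)
             else choose_min_n(elbows$male, elbows$female)
  } else {
    min_n <- as.integer(cfg$min_n)
  }

  # ---- filter and select --------------------------------------------------
  filtered <- .stage("filter_min_n",
                     suppressMessages(filter_min_n(records, min_n)))
  selected <- .stage("select_best_population",
                     select_best_population(filtered))

  # ---- classify -----------------------------------------------------------
  classified <- .stage("classify",
                       classify_dimorphism(selected, alpha = cfg$alpha,
                                           method = cfg$ci_method))
  ratios <- suppressMessages(ratio_summary(classified))

  # ---- resample -----------------------------------------------------------
  rates <- .stage("resample", do.call(resample_rates, c(
    list(classified = classified, richness = richness),
    cfg$resample)))

  # ---- SD tests -----------------------------------------------------------
  sd_tests <- .stage("sd_tests", sd_summary(classified))

  # ---- manifest and outputs ----------------------------------------------
  class_counts <- as.list(table(classified$class))
  manifest <- list(
    package = "ssdrates",
    version = as.character(utils::packageVersion("ssdrates")),
    config = cfg[setdiff(names(cfg), "write_plots")],
    input_digests = digests,
    seed = cfg$resample$seed,
    counts = list(
      populations_ingested = n_ingested,
      populations_after_pooling = nrow(records),
      removed_by_min_n = nrow(records) - nrow(filtered),
      populations_after_min_n = nrow(filtered),
      species_retained = nrow(classified),
      per_class = class_counts
    ),
    min_n = min_n,
    elbows = if (!is.null(elbows)) {
      list(male = elbows$male$elbow_x, female = elbows$female$elbow_x)
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      dplyr::mutate(classified, class = as.character(.data$class)),
      file.path(out_dir, "classified.csv"), progress = FALSE)
    rate_report(rates, file.path(out_dir, "rates.csv"))
    readr::write_csv(sd_tests, file.path(out_dir, "sd_summary.csv"),
                     progress = FALSE)
    readr::write_csv(ratios, file.path(out_dir, "ratio_summary.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (isTRUE(cfg$write_plots)) {
      if (!is.null(elbows)) {
        ggplot2::ggsave(file.path(out_dir, "cutoff_male.png"),
                        plot_cutoff_fit(elbows$male),
                        width = 6, height = 4, dpi = 150)
        ggplot2::ggsave(file.path(out_dir, "cutoff_female.png"),
                        plot_cutoff_fit(elbows$female),
                        width = 6, height = 4, dpi = 150)
      }
      ggplot2::ggsave(file.path(out_dir, "rates.png"),
                      plot_rate_estimates(rates),
                      width = 7, height = 5, dpi = 150)
    }
  }

  invisible(list(records = records, elbows = elbows, min_n = min_n,
                 classified = classified, rates = rates, ratios = ratios,
                 sd_tests = sd_tests, truth = truth, manifest = manifest))
}
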