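#' Run configuration for the reporting front end
#'
#' Collects every input a reporting run needs: the cohort file, economic
#' parameters, probability rounding mode, commodity file, output directory and
#' seed. All reports are deterministic given a config (plus its seed), and the
#' JSON metadata record written next to each report suffices to reproduce it.
#'
#' @param cohort_file path to a cohort CSV; default the packaged historical
#'   fixture.
#' @param econ an [econ_params()] object.
#' @param mode probability rounding mode, see [derive_transitions()].
#' @param commodity_file path to a supplement commodity CSV; default the
#'   packaged fixture.
#' @param out_dir directory reports are written into (created if absent).
#' @param seed integer seed for stochastic commands.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort_file = NULL, econ = econ_params(),
                       mode = c("percentages", "counts"),
                       commodity_file = NULL, out_dir = ".", seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cohort_file)) {
    cohort_file <- system.file("extdata", "zambia_cohort.csv",
      package = "nutricea", mustWork = TRUE
    )
  }
  if (is.null(commodity_file)) {
    commodity_file <- system.file("extdata", "supplements.csv",
      package = "nutricea", mustWork = TRUE
    )
  }
  if (!file.exists(cohort_file)) {
    abort(paste0("cohort file not found: ", cohort_file), class = "nutricea_io_error")
  }
  if (!file.exists(commodity_file)) {
    abort(paste0("commodity file not found: ", commodity_file), class = "nutricea_io_error")
  }
  structure(
    list(
      cohort_file = cohort_file, econ = econ, mode = mode,
      commodity_file = commodity_file, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# Internal: write a tidy CSV plus a JSON run-metadata record; returns the
# result invisibly so report functions compose in pipelines.
.write_report <- function(result, config, name, extra_meta = list()) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  csv_path <- file.path(config$out_dir, paste0(name, ".csv"))
  readr::write_csv(as_tibble(result), csv_path)
  meta <- c(
    list(
      command = name,
      cohort_file = config$cohort_file,
      commodity_file = config$commodity_file,
      mode = config$mode,
      seed = config$seed,
      econ = unclass(config$econ),
      package_version = as.character(utils::packageVersion("nutricea")),
      rows_written = nrow(result)
    ),
    extra_meta
  )
  jsonlite::write_json(meta, file.path(config$out_dir, paste0(name, "_run.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(result)
}

#' Reporting commands
#'
#' Each `report_*()` function runs one pipeline stage on a [run_config()],
#' writes a tidy CSV plus a JSON run-metadata record into the config's output
#' directory, and returns the result tibble invisibly. They back the
#' subcommands of the packaged command-line script
#' (`system.file("cli", "nutricea.R", package = "nutricea")`).
#'
#' * `report_wtp()`: per-stratum willingness-to-pay benchmarks.
#' * `report_thresholds()`: the scenario matrix of threshold prices; pass
#'   `scenarios` to override the four published ones.
#' * `report_surface()`: the retention surface grid.
#' * `report_frontier()`: parity frontiers for the given quarterly prices.
#' * `report_sensitivity()`: ART-cost sweep and LTFU return-to-care sweep.
#' * `report_supplements()`: commodity costing and affordability verdicts.
#' * `report_simulate()`: a synthetic cohort drawn at the config's seed from
#'   the cohort file's raw-count transitions.
#'
#' @param config a [run_config()].
#' @param scenarios optional scenario tibble (`scenario`, `r_mort`, `r_ltfu`).
#' @return the result tibble, invisibly.
#' @name reporting
#' @export
report_wtp <- function(config) {
  cohort <- load_cohort_table(config$cohort_file)
  .write_report(willingness_to_pay(cohort, config$econ, mode = config$mode),
    config, "wtp"
  )
}

#' @rdname reporting
#' @export
report_thresholds <- function(config, scenarios = .default_scenarios()) {
  cohort <- load_cohort_table(config$cohort_file)
  strata <- intersect(malnourished_strata(), unique(cohort$stratum))
  .write_report(
    scenario_table(cohort, config$econ,
      scenarios = scenarios, strata = strata, mode = config$mode
    ),
    config, "thresholds"
  )
}

#' @rdname reporting
#' @inheritParams retention_surface
#' @export
report_surface <- function(config, r_mort_grid = seq(0, 0.5, by = 0.05),
                           r_ltfu_grid = seq(0, 0.5, by = 0.1)) {
  cohort <- load_cohort_table(config$cohort_file)
  .write_report(
    retention_surface(cohort,
      r_mort_grid = r_mort_grid, r_ltfu_grid = r_ltfu_grid, mode = config$mode
    ),
    config, "surface"
  )
}

#' @rdname reporting
#' @param supplement_costs quarterly prices to trace frontiers for.
#' @param resolution frontier grid resolution, see [parity_frontier()].
#' @export
report_frontier <- function(config, supplement_costs = c(5, 10, 15, 25),
                            resolution = 0.01) {
  cohort <- load_cohort_table(config$cohort_file)
  res <- purrr::map_dfr(
    supplement_costs,
    ~ parity_frontier(cohort, config$econ, .x, resolution = resolution, mode = config$mode)
  )
  .write_report(res, config, "frontier")
}

#' @rdname reporting
#' @param annual_costs ART-cost sweep grid (USD per patient-year).
#' @param return_fractions LTFU return-to-care sweep grid.
#' @param r_mort,r_ltfu intervention effect assumed in both sweeps.
#' @export
report_sensitivity <- function(config, annual_costs = seq(500, 1200, by = 25),
                               return_fractions = seq(0.2, 0.8, by = 0.1),
                               r_mort = 0.2, r_ltfu = 0.2) {
  cohort <- load_cohort_table(config$cohort_file)
  art <- art_cost_sweep(cohort,
    annual_costs = annual_costs, r_mort = r_mort, r_ltfu = r_ltfu,
    base_econ = config$econ, mode = config$mode
  ) %>%
    mutate(analysis = "art_cost", parameter_value = .data$annual_art_cost)
  ret <- ltfu_return_threshold(cohort,
    return_fractions = return_fractions, r_mort = r_mort, r_ltfu = r_ltfu,
    econ = config$econ, mode = config$mode
  ) %>%
    mutate(analysis = "ltfu_return", parameter_value = .data$return_fraction)
  res <- bind_rows(
    art[, c("analysis", "stratum", "parameter_value", "wtp", "s_star")],
    ret[, c("analysis", "stratum", "parameter_value", "wtp", "s_star")]
  )
  .write_report(res, config, "sensitivity")
}

#' @rdname reporting
#' @export
report_supplements <- function(config) {
  cohort <- load_cohort_table(config$cohort_file)
  products <- supplement_products(config$commodity_file)
  strata <- intersect(malnourished_strata(), unique(cohort$stratum))
  sc <- scenario_table(cohort, config$econ, strata = strata, mode = config$mode)
  .write_report(affordability_report(products, sc), config, "supplements")
}

#' @rdname reporting
#' @param n_start quarter-1 cohort size per stratum for the simulation;
#'   default the sizes in the config's cohort file.
#' @export
report_simulate <- function(config, n_start = NULL) {
  cohort <- load_cohort_table(config$cohort_file)
  truth <- derive_transitions(cohort, mode = "counts")
  if (is.null(n_start)) {
    q1 <- cohort[cohort$quarter == 1, ]
    n_start <- stats::setNames(q1$n_entering, q1$stratum)
  }
  .write_report(
    simulate_cohort(truth, n_start, seed = config$seed),
    config, "simulated_cohort",
    extra_meta = list(n_start = as.list(n_start))
  )
}
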