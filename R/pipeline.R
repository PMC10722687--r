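# Pipeline entry points tying the stages together: validate a bundle, run
# impact -> costing -> ROI -> budget impact, and write the report files.

fmt_usd <- function(x, digits = 2) {
  paste0("US$", formatC(x, format = "f", digits = digits, big.mark = ","))
}

#' Run the full investment-case pipeline and write a report bundle
#'
#' Validates the configuration, projects lives saved, rolls up national
#' costs, runs the return-on-investment analysis, and writes: the impact
#' projection as tidy CSV; per-hospital and national cost breakdowns as CSV;
#' the ROI components and budget impact as JSON; and a human-readable summary
#' mirroring the investment-case worksheet rows. All machine-readable outputs
#' keep full precision; display rounding happens only in the summary text.
#'
#' @param bundle A configuration bundle or a path to a bundle directory.
#' @param out_dir Output directory (created if needed).
#' @param scenario Costing scenario, `"A"` or `"B"`.
#' @param horizon Final year of the investment window.
#' @param monetisation `"gdp_multiplier"` or `"vsl"`.
#' @param ... Passed on to [roi_analysis()].
#' @return Invisibly, a list with `impact`, `costs`, `roi` and the written
#'   `paths`. Errors (listing every failed invariant) before writing anything
#'   if the bundle does not validate.
#' @examples
#' \donttest{
#' out <- run_pipeline(tanzania_fixture(), tempfile("ssnc-report-"))
#' }
#' @export
run_pipeline <- function(bundle, out_dir, scenario = "A", horizon = 2030,
                         monetisation = c("gdp_multiplier", "vsl"), ...) {
  monetisation <- match.arg(monetisation)
  if (is.character(bundle)) bundle <- read_bundle(bundle, check = FALSE)
  problems <- validate_bundle(bundle, collect = TRUE)
  if (length(problems)) {
    rlang::abort(
      paste0("bundle validation failed:\n",
             paste0("  - ", problems, collapse = "\n")),
      class = "ssnc_invalid_bundle"
    )
  }
  base_year <- bundle$base_year
  roi <- roi_analysis(bundle, scenario = scenario, horizon = horizon,
                      monetisation = monetisation, ...)
  impact <- roi$impact
  costs <- roi$costs

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    impact = file.path(out_dir, "impact_projection.csv"),
    per_hospital = file.path(out_dir, "cost_breakdown_per_hospital.csv"),
    by_level = file.path(out_dir, "cost_by_level.csv"),
    roi = file.path(out_dir, "roi.json"),
    budget = file.path(out_dir, "budget_impact.json"),
    summary = file.path(out_dir, "summary.txt")
  )
  readr::write_csv(tidy(impact), paths$impact)
  readr::write_csv(tidy(costs), paths$per_hospital)
  readr::write_csv(costs$by_level, paths$by_level)
  jsonlite::write_json(
    list(summary = as.list(glance(roi)),
         components = tidy(roi)),
    paths$roi, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(as.list(roi$budget), paths$budget,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(pipeline_summary_lines(bundle, roi), paths$summary)
  invisible(list(impact = impact, costs = costs, roi = roi, paths = paths))
}

pipeline_summary_lines <- function(bundle, roi) {
  s <- roi$summary
  costs <- roi$costs
  impact <- roi$impact
  n_years <- s$horizon - roi$conventions$base_year + 1

  setup_rows <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(costs$per_hospital, .data$kind == "setup"),
      .data$category
    ),
    annualised = sum(.data$annualised *
                       costs$by_level$n_hospitals[match(.data$level,
                                                        costs$by_level$level)]),
    .groups = "drop"
  )
  c(
    paste0("SSNC investment case - ", bundle$country, ", scenario ",
           s$scenario, ", ", roi$conventions$base_year, "-", s$horizon),
    "",
    "Impact",
    paste0("  Baseline neonatal deaths/year: ",
           formatC(impact$baseline_deaths, format = "f", digits = 0,
                   big.mark = ",")),
    paste0("  Cumulative lives saved by ", s$horizon, ": ",
           formatC(s$lives_saved, format = "f", digits = 0, big.mark = ",")),
    paste0("  NMR in ", s$horizon, ": ",
           round(impact$data$nmr[nrow(impact$data)], 1),
           " per 1000 live births"),
    "",
    "Setup costs (annualised | to horizon)",
    vapply(seq_len(nrow(setup_rows)), function(i) {
      paste0("  ", format(setup_rows$category[i], width = 24), " ",
             fmt_usd(setup_rows$annualised[i]), " | ",
             fmt_usd(setup_rows$annualised[i] * n_years))
    }, character(1)),
    paste0("  ", format("Total setup costs", width = 24), " ",
           fmt_usd(costs$national$setup_annualised), " | ",
           fmt_usd(s$setup_costs_to_horizon)),
    "",
    "Running costs (gradual implementation)",
    vapply(seq_len(nrow(roi$running_stream)), function(i) {
      paste0("  ", roi$running_stream$year[i], "  ",
             formatC(100 * roi$running_stream$fraction[i], format = "f",
                     digits = 0), "%  ",
             fmt_usd(roi$running_stream$cost[i]))
    }, character(1)),
    paste0("  Total running costs ", fmt_usd(sum(roi$running_stream$cost))),
    "",
    "Monetised health benefits",
    paste0("  Years of life lost averted: ",
           formatC(s$yll_averted, format = "f", digits = 0, big.mark = ",")),
    paste0("  Value per life-year (", s$monetisation, "): ",
           fmt_usd(s$value_per_life_year)),
    paste0("  Monetised lives saved (future value): ",
           fmt_usd(s$social_benefit_fv)),
    paste0("  Monetised lives saved (present value): ",
           fmt_usd(s$social_benefit_pv)),
    paste0("  Productivity gains (future value): ", fmt_usd(s$productivity_fv)),
    paste0("  Productivity gains (present value): ", fmt_usd(s$productivity_pv)),
    "",
    "Return on investment",
    paste0("  Total costs to ", s$horizon, ": ", fmt_usd(s$total_costs_pv)),
    paste0("  Total ROI: ", formatC(s$roi_total, format = "f", digits = 1)),
    paste0("  Cost per death averted: ", fmt_usd(s$cost_per_death_averted)),
    "",
    "Budget impact",
    paste0("  Cost per capita: ", fmt_usd(roi$budget$cost_per_capita)),
    paste0("  Cost per birth: ", fmt_usd(roi$budget$cost_per_birth)),
    paste0("  Share of health expenditure per capita: ",
           formatC(100 * roi$budget$share_of_the, format = "f", digits = 1),
           "%")
  )
}

#' Compare scale-up scenarios on one bundle
#'
#' Runs the national roll-up under two scenarios and reports side-by-side
#' totals with deltas. For the standard scenario rules (B acquires a subset
#' of A) every delta must be non-negative; a violation signals an
#' inconsistent bundle and raises an error.
#'
#' @param bundle A configuration bundle or bundle directory path.
#' @param scenario_a,scenario_b Scenario names to compare (defaults A vs B).
#' @param check_ordering Error if any scenario-B cost exceeds scenario A.
#' @return A tibble with one row per cost metric: `metric`, `level`,
#'   value under each scenario, and `delta` (first minus second).
#' @examples
#' compare_scenarios(tanzania_fixture())
#' @export
compare_scenarios <- function(bundle, scenario_a = "A", scenario_b = "B",
                              check_ordering = TRUE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  roll_a <- national_rollout(bundle, scenario_a)
  roll_b <- national_rollout(bundle, scenario_b)
  metrics <- c("setup_total", "setup_annualised", "running_annual",
               "annual_total")
  rows <- dplyr::bind_rows(
    dplyr::select(roll_a$by_level, "level", dplyr::all_of(metrics)),
    dplyr::mutate(dplyr::select(roll_a$national, dplyr::all_of(metrics)),
                  level = "national")
  )
  rows_b <- dplyr::bind_rows(
    dplyr::select(roll_b$by_level, "level", dplyr::all_of(metrics)),
    dplyr::mutate(dplyr::select(roll_b$national, dplyr::all_of(metrics)),
                  level = "national")
  )
  long_a <- tidyr::pivot_longer(rows, dplyr::all_of(metrics),
                                names_to = "metric", values_to = "value_a")
  long_b <- tidyr::pivot_longer(rows_b, dplyr::all_of(metrics),
                                names_to = "metric", values_to = "value_b")
  out <- dplyr::mutate(
    dplyr::left_join(long_a, long_b, by = c("level", "metric")),
    delta = .data$value_a - .data$value_b
  )
  names(out)[names(out) == "value_a"] <- paste0("scenario_", scenario_a)
  names(out)[names(out) == "value_b"] <- paste0("scenario_", scenario_b)
  if (check_ordering && scenario_a == "A" && scenario_b == "B" &&
      any(out$delta < -1e-6 * pmax(out[[3]], 1))) {
    stop_invalid("scenario B exceeds scenario A for some cost metric; ",
                 "bundle scenario rules are inconsistent")
  }
  out
}
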