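# Return on investment: phased cost streams, discounting, monetisation of
# lives saved, cost-benefit ratios, and budget impact.
#
# Conventions (all configurable, defaults reproduce the worked Tanzania
# tables): costs-to-horizon for capital = annualised setup x number of years;
# running costs follow a gradual implementation schedule and are discounted
# with a single simple 3% reduction ("simple"), year-by-year NPV ("annual")
# also being available; benefits are a lump sum discounted over one life
# expectancy.

#' Monetisation parameters for valuing averted life-years
#'
#' @param method `"gdp_multiplier"` (value of a life-year = multiplier x GDP
#'   per capita) or `"vsl"` (a literature value of a statistical life-year).
#' @param gdp_per_capita GDP per capita, USD/year.
#' @param gdp_multiplier Multiplier on GDP per capita (default 2.3).
#' @param vsl_year Value of a statistical life-year, USD (required for the
#'   `"vsl"` method).
#' @param gdp_growth Assumed annual GDP growth applied when
#'   `use_gdp_growth = TRUE` in [roi_analysis()].
#' @param discount_rate Annual discount rate for benefits.
#' @param labour_entry_age Age of labour-force entry (years).
#' @param productive_years Productive life-years after labour-force entry.
#' @return A one-row tibble of monetisation parameters.
#' @export
monetisation_spec <- function(method = c("gdp_multiplier", "vsl"),
                              gdp_per_capita, gdp_multiplier = 2.3,
                              vsl_year = NA_real_, gdp_growth = 0.03,
                              discount_rate = 0.03, labour_entry_age = 20,
                              productive_years = 46) {
  method <- match.arg(method)
  check_number(gdp_per_capita, "gdp_per_capita", lower = 0, strict_lower = TRUE)
  check_number(discount_rate, "discount_rate", lower = 0)
  if (method == "vsl" && (is.na(vsl_year) || vsl_year <= 0)) {
    stop_invalid("vsl method requires a positive vsl_year")
  }
  tibble::tibble(
    method = method, gdp_per_capita = gdp_per_capita,
    gdp_multiplier = gdp_multiplier, vsl_year = vsl_year,
    gdp_growth = gdp_growth, discount_rate = discount_rate,
    labour_entry_age = labour_entry_age, productive_years = productive_years
  )
}

#' Capital cost stream to the horizon
#'
#' Cost of annualised capital over the investment window: the equivalent
#' annual setup cost multiplied by the number of years.
#'
#' @param annualised_setup Equivalent annual setup cost, USD/year.
#' @param years Number of years in the window (>= 0).
#' @return Total setup cost attributed to the window, USD.
#' @examples
#' setup_stream(10731570, 10)
#' @export
setup_stream <- function(annualised_setup, years) {
  if (any(annualised_setup < 0)) stop_invalid("annualised_setup must be >= 0")
  if (years < 0) stop_invalid("years must be >= 0")
  annualised_setup * years
}

validate_schedule <- function(schedule) {
  check_columns(schedule, c("year", "fraction"), "schedule")
  if (any(schedule$fraction <= 0) || any(schedule$fraction > 1)) {
    stop_invalid("schedule fractions must lie in (0, 1]")
  }
  if (is.unsorted(schedule$fraction)) {
    stop_invalid("schedule fractions must be non-decreasing")
  }
  if (abs(schedule$fraction[nrow(schedule)] - 1) > 1e-12) {
    stop_invalid("final schedule fraction must be 1.0")
  }
  invisible(schedule)
}

#' Running-cost stream under gradual implementation
#'
#' Scales the full annual running cost by the fraction of facilities
#' operational each year.
#'
#' @param full_annual_running Annual running cost at full implementation,
#'   USD/year.
#' @param schedule Implementation schedule: tibble with `year` and `fraction`
#'   (in (0,1], non-decreasing, final year 1.0).
#' @return A tibble with `year`, `fraction`, `cost`; the undiscounted stream
#'   total is `sum(.$cost)`.
#' @examples
#' sched <- tibble::tibble(year = 2021:2030,
#'   fraction = c(.25, .30, .35, .40, .55, .60, .70, .85, .90, 1))
#' running_stream(47e6, sched)
#' @export
running_stream <- function(full_annual_running, schedule) {
  check_number(full_annual_running, "full_annual_running", lower = 0)
  validate_schedule(schedule)
  dplyr::mutate(schedule, cost = .data$fraction * full_annual_running)
}

#' Net present value of an annual stream
#'
#' End-of-period convention: a value in `base_year` is undiscounted and a
#' value `k` years later is divided by `(1 + rate)^k`.
#'
#' @param stream Either a data frame with a `year` column and one numeric
#'   value column (e.g. `cost`), or a numeric vector named by year.
#' @param rate Annual discount rate (>= 0).
#' @param base_year Year with discount factor 1; defaults to the stream's
#'   first year.
#' @return Present value in USD.
#' @export
npv <- function(stream, rate, base_year = NULL) {
  check_number(rate, "rate", lower = 0)
  if (is.data.frame(stream)) {
    check_columns(stream, "year", "stream")
    value_col <- setdiff(names(stream)[vapply(stream, is.numeric, logical(1))],
                         c("year", "fraction"))
    if (!length(value_col)) stop_invalid("stream has no numeric value column")
    years <- stream$year
    values <- stream[[value_col[1]]]
  } else {
    if (is.null(names(stream))) stop_invalid("a vector stream must be named by year")
    years <- as.numeric(names(stream))
    values <- as.numeric(stream)
  }
  base_year <- base_year %||% min(years)
  sum(values / (1 + rate)^(years - base_year))
}

#' Monetary value of one averted life-year
#'
#' @param spec A [monetisation_spec()].
#' @return USD per life-year: `gdp_multiplier x gdp_per_capita` under the GDP
#'   approach, or the statistical life-year value under the VSL approach.
#' @export
value_per_life_year <- function(spec) {
  check_columns(spec, c("method", "gdp_per_capita", "gdp_multiplier", "vsl_year"),
                "spec")
  if (spec$method == "gdp_multiplier") {
    spec$gdp_multiplier * spec$gdp_per_capita
  } else {
    spec$vsl_year
  }
}

#' Monetise lives saved as years of life lost averted
#'
#' @param lives Deaths averted.
#' @param life_expectancy Life expectancy at birth, years.
#' @param value_year USD per life-year.
#' @return A tibble with `yll` (averted years of life lost,
#'   `lives x life_expectancy`) and `future_value`
#'   (`yll x value_year`, USD, undiscounted).
#' @examples
#' monetise_lives(80000, 66, 2527.7)
#' @export
monetise_lives <- function(lives, life_expectancy, value_year) {
  check_number(lives, "lives", lower = 0)
  check_number(life_expectancy, "life_expectancy", lower = 0)
  check_number(value_year, "value_year", lower = 0)
  yll <- lives * life_expectancy
  tibble::tibble(yll = yll, future_value = yll * value_year)
}

#' Future-value productivity gains from averted deaths
#'
#' @param lives Deaths averted.
#' @param productive_years Productive life-years per person.
#' @param value_year USD per life-year.
#' @return `lives x productive_years x value_year`, USD (future value).
#' @export
productivity_gains <- function(lives, productive_years, value_year) {
  check_number(lives, "lives", lower = 0)
  check_number(productive_years, "productive_years", lower = 0)
  check_number(value_year, "value_year", lower = 0)
  lives * productive_years * value_year
}

#' Present value of a lump-sum future benefit
#'
#' The stream of monetised life-years is treated as a lump sum realised
#' `horizon_years` ahead (by default one life expectancy) and discounted once.
#'
#' @param future_value Future value, USD.
#' @param rate Annual discount rate.
#' @param horizon_years Years over which to discount.
#' @return `future_value / (1 + rate)^horizon_years`.
#' @export
present_value_of_benefit <- function(future_value, rate, horizon_years) {
  check_number(future_value, "future_value", lower = 0)
  check_number(rate, "rate", lower = 0)
  check_number(horizon_years, "horizon_years", lower = 0)
  future_value / (1 + rate)^horizon_years
}

#' Return on investment (benefit-cost ratio)
#'
#' @param costs_pv Present value of costs, USD (> 0).
#' @param social_pv Present value of monetised lives saved, USD.
#' @param productivity_pv Present value of productivity gains, USD.
#' @return `(social_pv + productivity_pv) / costs_pv`.
#' @export
compute_roi <- function(costs_pv, social_pv, productivity_pv) {
  check_number(social_pv, "social_pv", lower = 0)
  check_number(productivity_pv, "productivity_pv", lower = 0)
  if (!is.numeric(costs_pv) || length(costs_pv) != 1L || is.na(costs_pv) ||
      costs_pv <= 0) {
    stop_invalid("costs_pv must be a single positive number")
  }
  (social_pv + productivity_pv) / costs_pv
}

#' Budget impact of an annual programme cost
#'
#' @param annual_cost Annual programme cost, USD/year.
#' @param profile A [country_profile()].
#' @return A tibble with `cost_per_capita`, `cost_per_birth` and
#'   `share_of_the` (cost per capita as a proportion of total health
#'   expenditure per capita).
#' @examples
#' budget_impact(57e6, country_profile(61.5e6, 2.15e6, 20, 66, 1099, 40.62))
#' @export
budget_impact <- function(annual_cost, profile) {
  check_number(annual_cost, "annual_cost", lower = 0)
  check_columns(profile, c("population", "annual_births", "the_per_capita"),
                "profile")
  cost_per_capita <- annual_cost / profile$population
  tibble::tibble(
    cost_per_capita = cost_per_capita,
    cost_per_birth = annual_cost / profile$annual_births,
    share_of_the = cost_per_capita / profile$the_per_capita
  )
}

# full Step-4/5 wrapper -------------------------------------------------------

#' Full return-on-investment analysis for a configuration bundle
#'
#' Runs the impact projection and national costing, builds the phased cost
#' streams, monetises lives saved, and reports the benefit-cost ratio, cost
#' per death averted and budget-impact metrics.
#'
#' @param bundle A configuration bundle ([tanzania_fixture()] or
#'   [generate_bundle()]).
#' @param scenario Costing scenario, `"A"` or `"B"`.
#' @param horizon Final year of the investment window.
#' @param monetisation `"gdp_multiplier"` or `"vsl"`.
#' @param running_basis `"schedule"` scales running costs by the bundle's
#'   implementation schedule; `"coverage"` scales them by the mean
#'   intervention coverage trajectory instead (a sensitivity analysis).
#' @param cost_discounting How the running-cost stream total is discounted:
#'   `"simple"` (one flat reduction of `rate`, the convention of the worked
#'   example), `"annual"` (end-of-year NPV from the base year) or `"none"`.
#' @param use_gdp_growth If `TRUE`, the value of a life-year grows at the
#'   monetisation spec's `gdp_growth` over the investment window before
#'   monetisation (constant-value otherwise).
#' @param interventions Optional replacement intervention table (e.g. from
#'   [halve_effectiveness()]).
#' @return An object of class `ssnc_roi`. [glance()] gives the headline
#'   scalars; [tidy()] gives a labelled component table mirroring the
#'   investment-case worksheets; `$budget` holds the [budget_impact()] row.
#' @examples
#' tz <- tanzania_fixture()
#' glance(roi_analysis(tz))
#' @export
roi_analysis <- function(bundle, scenario = "A", horizon = 2030,
                         monetisation = c("gdp_multiplier", "vsl"),
                         running_basis = c("schedule", "coverage"),
                         cost_discounting = c("simple", "annual", "none"),
                         use_gdp_growth = FALSE,
                         interventions = NULL) {
  monetisation <- match.arg(monetisation)
  running_basis <- match.arg(running_basis)
  cost_discounting <- match.arg(cost_discounting)
  interventions <- interventions %||% bundle$interventions
  base_year <- bundle$base_year %||% min(bundle$schedule$year)

  impact <- project_impact(bundle$profile, interventions, bundle$cause_shares,
                           start_year = base_year, horizon = horizon)
  lives <- impact$data$cumulative_lives_saved[nrow(impact$data)]

  costs <- national_rollout(bundle, scenario)
  n_years <- horizon - base_year + 1
  setup_to_horizon <- setup_stream(costs$national$setup_annualised, n_years)

  mspec <- bundle$monetisation
  mspec$method <- monetisation
  rate <- mspec$discount_rate

  if (running_basis == "schedule") {
    schedule <- dplyr::filter(bundle$schedule, .data$year <= horizon)
    running <- running_stream(costs$national$running_annual, schedule)
  } else {
    cov_by_year <- purrr::map(seq_len(nrow(interventions)), function(i) {
      build_trajectory(interventions$baseline_coverage[i],
                       interventions$target_coverage[i],
                       base_year, horizon)$coverage
    })
    schedule <- tibble::tibble(
      year = seq(base_year, horizon),
      fraction = purrr::reduce(cov_by_year, `+`) / length(cov_by_year)
    )
    # the coverage ramp need not end at full implementation, so it is not
    # pushed through the schedule validator
    running <- dplyr::mutate(schedule,
                             cost = .data$fraction * costs$national$running_annual)
  }
  running_undiscounted <- sum(running$cost)
  running_to_horizon <- switch(
    cost_discounting,
    simple = running_undiscounted * (1 - rate),
    annual = npv(running, rate, base_year),
    none = running_undiscounted
  )
  total_costs <- setup_to_horizon + running_to_horizon

  value_year <- value_per_life_year(mspec)
  if (use_gdp_growth) {
    value_year <- value_year * (1 + mspec$gdp_growth)^(horizon - base_year)
  }
  life_expectancy <- bundle$profile$life_expectancy
  social <- monetise_lives(lives, life_expectancy, value_year)
  social_pv <- present_value_of_benefit(social$future_value, rate, life_expectancy)
  prod_fv <- productivity_gains(lives, mspec$productive_years, value_year)
  prod_horizon <- mspec$labour_entry_age + mspec$productive_years
  prod_pv <- present_value_of_benefit(prod_fv, rate, prod_horizon)

  roi_total <- if (total_costs > 0) {
    compute_roi(total_costs, social_pv, prod_pv)
  } else {
    NA_real_
  }

  summary <- tibble::tibble(
    scenario = costs$scenario,
    horizon = horizon,
    monetisation = monetisation,
    lives_saved = lives,
    setup_costs_to_horizon = setup_to_horizon,
    running_costs_to_horizon = running_to_horizon,
    total_costs_pv = total_costs,
    yll_averted = social$yll,
    value_per_life_year = value_year,
    social_benefit_fv = social$future_value,
    social_benefit_pv = social_pv,
    productivity_fv = prod_fv,
    productivity_pv = prod_pv,
    roi_total = roi_total,
    cost_per_death_averted = if (lives > 0) total_costs / lives else NA_real_
  )
  structure(
    list(
      summary = summary,
      budget = budget_impact(costs$national$annual_total, bundle$profile),
      running_stream = running,
      impact = impact,
      costs = costs,
      conventions = list(running_basis = running_basis,
                         cost_discounting = cost_discounting,
                         use_gdp_growth = use_gdp_growth,
                         base_year = base_year)
    ),
    class = "ssnc_roi"
  )
}

#' @export
print.ssnc_roi <- function(x, ...) {
  s <- x$summary
  cat("SSNC return on investment, scenario ", s$scenario, " to ", s$horizon,
      " (", s$monetisation, " monetisation)\n", sep = "")
  cat("  lives saved:            ", format(round(s$lives_saved), big.mark = ","), "\n")
  cat("  total costs to horizon:  US$",
      format(round(s$total_costs_pv), big.mark = ","), "\n", sep = "")
  cat("  benefit PV (social):     US$",
      format(round(s$social_benefit_pv), big.mark = ","), "\n", sep = "")
  cat("  benefit PV (productivity): US$",
      format(round(s$productivity_pv), big.mark = ","), "\n", sep = "")
  cat("  ROI:                    ", round(s$roi_total, 2), "\n")
  cat("  cost per death averted:  US$",
      format(round(s$cost_per_death_averted), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @rdname roi_analysis
#' @param x,object An `ssnc_roi` object.
#' @param ... Unused.
#' @method glance ssnc_roi
#' @export
glance.ssnc_roi <- function(x, ...) x$summary

#' @rdname roi_analysis
#' @method tidy ssnc_roi
#' @export
tidy.ssnc_roi <- function(x, ...) {
  s <- x$summary
  b <- x$budget
  tibble::tibble(
    component = c(
      "setup costs to horizon", "running costs to horizon",
      "total costs to horizon", "lives saved", "years of life lost averted",
      "value per life-year", "monetised lives saved (future value)",
      "monetised lives saved (present value)",
      "productivity gains (future value)", "productivity gains (present value)",
      "total ROI", "cost per death averted", "cost per capita",
      "cost per birth", "share of health expenditure per capita"
    ),
    value = c(
      s$setup_costs_to_horizon, s$running_costs_to_horizon, s$total_costs_pv,
      s$lives_saved, s$yll_averted, s$value_per_life_year,
      s$social_benefit_fv, s$social_benefit_pv, s$productivity_fv,
      s$productivity_pv, s$roi_total, s$cost_per_death_averted,
      b$cost_per_capita, b$cost_per_birth, b$share_of_the
    )
  )
}

#' @rdname roi_analysis
#' @method autoplot ssnc_roi
#' @export
autoplot.ssnc_roi <- function(object, ...) {
  s <- object$summary
  df <- tibble::tibble(
    component = factor(
      c("Costs", "Social benefit", "Productivity benefit"),
      levels = c("Costs", "Social benefit", "Productivity benefit")
    ),
    value = c(s$total_costs_pv, s$social_benefit_pv, s$productivity_pv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value / 1e6)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "US$ million (present value)",
                  title = paste0("Discounted costs and benefits to ", s$horizon,
                                 " (ROI ", round(s$roi_total, 1), ")")) +
    ggplot2::theme_minimal()
}

#' Sensitivity analyses around the base return-on-investment run
#'
#' Reruns the analysis with (i) value-of-statistical-life monetisation in
#' place of the GDP multiplier, (ii) running costs scaled by the intervention
#' coverage trajectory instead of the implementation schedule, and (iii) a
#' lower-quality-of-care impact projection in which high-impact interventions
#' operate at half effectiveness (supportive care for intrapartum and
#' congenital conditions exempt).
#'
#' @param bundle A configuration bundle.
#' @param horizon Final year of the investment window.
#' @param exempt Intervention names whose effectiveness is not halved in the
#'   quality sensitivity; defaults to interventions on intrapartum and
#'   congenital causes.
#' @param quality_horizon Horizon for the halved-effectiveness projection
#'   (default base year + 4, the national-target window).
#' @return A list of class `ssnc_sensitivity`: `$comparison` (one row per
#'   costed run: base, VSL, coverage-scaled running costs) and
#'   `$halved_effectiveness` (summary of the degraded-quality projection).
#' @export
sensitivity_suite <- function(bundle, horizon = 2030, exempt = NULL,
                              quality_horizon = NULL) {
  base <- roi_analysis(bundle, horizon = horizon)
  vsl <- roi_analysis(bundle, horizon = horizon, monetisation = "vsl")
  cov_run <- roi_analysis(bundle, horizon = horizon, running_basis = "coverage")
  comparison <- dplyr::bind_rows(
    dplyr::mutate(base$summary, analysis = "base", .before = 1),
    dplyr::mutate(vsl$summary, analysis = "vsl_monetisation", .before = 1),
    dplyr::mutate(cov_run$summary, analysis = "coverage_running_costs",
                  .before = 1)
  )
  base_year <- bundle$base_year %||% min(bundle$schedule$year)
  if (is.null(exempt)) {
    exempt <- bundle$interventions$name[
      bundle$interventions$cause %in% c("intrapartum", "congenital")
    ]
  }
  quality_horizon <- quality_horizon %||% (base_year + 4)
  halved <- halve_effectiveness(bundle$interventions, exempt = exempt)
  impact_b <- project_impact(bundle$profile, halved, bundle$cause_shares,
                             start_year = base_year, horizon = quality_horizon)
  structure(
    list(comparison = comparison,
         halved_effectiveness = glance(impact_b)),
    class = "ssnc_sensitivity"
  )
}

#' @export
print.ssnc_sensitivity <- function(x, ...) {
  cat("SSNC sensitivity analyses\n")
  df <- dplyr::select(x$comparison, dplyr::all_of(
    c("analysis", "total_costs_pv", "social_benefit_pv", "productivity_pv",
      "roi_total", "cost_per_death_averted")
  ))
  print(as.data.frame(df), row.names = FALSE)
  he <- x$halved_effectiveness
  cat("halved effectiveness: NMR ", round(he$final_nmr, 1), " in ", he$horizon,
      ", cumulative lives saved ",
      format(round(he$cumulative_lives_saved), big.mark = ","), "\n", sep = "")
  invisible(x)
}
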