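# Deterministic projection of neonatal deaths averted under coverage scale-up.
#
# The model holds baseline-year births and cause-specific deaths constant over
# the horizon and, for each cause, converts coverage gains of the interventions
# acting on that cause into a proportional mortality reduction via a residual
# product so that several interventions on one cause are never double counted.

#' Construct a validated country profile
#'
#' Demographic and macro-economic constants read by every stage of the
#' investment case: the impact projection, national costing roll-up, and
#' budget-impact metrics.
#'
#' @param population Total population (persons).
#' @param annual_births Live births per year.
#' @param baseline_nmr Baseline neonatal mortality rate, deaths per 1000 live
#'   births, in (0, 1000).
#' @param life_expectancy Life expectancy at birth (years).
#' @param gdp_per_capita Gross domestic product per capita (USD/year).
#' @param the_per_capita Total health expenditure per capita (USD/year).
#' @param ssnc_need_fraction Proportion of live births requiring inpatient
#'   small-and-sick-newborn care, in (0, 1].
#' @param mean_admission_days Average inpatient admission length (days).
#'
#' @return A one-row tibble with the validated fields.
#' @examples
#' country_profile(61.5e6, 2.15e6, 20, 66, 1099, 40.62)
#' @export
country_profile <- function(population, annual_births, baseline_nmr,
                            life_expectancy, gdp_per_capita, the_per_capita,
                            ssnc_need_fraction = 0.10,
                            mean_admission_days = 7) {
  check_number(population, "population", lower = 0, strict_lower = TRUE)
  check_number(annual_births, "annual_births", lower = 0, strict_lower = TRUE)
  check_number(baseline_nmr, "baseline_nmr", lower = 0, upper = 1000,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(life_expectancy, "life_expectancy", lower = 0, strict_lower = TRUE)
  check_number(gdp_per_capita, "gdp_per_capita", lower = 0, strict_lower = TRUE)
  check_number(the_per_capita, "the_per_capita", lower = 0, strict_lower = TRUE)
  check_number(ssnc_need_fraction, "ssnc_need_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(mean_admission_days, "mean_admission_days", lower = 0,
               strict_lower = TRUE)
  fast_tibble(
    population = population, annual_births = annual_births,
    baseline_nmr = baseline_nmr, life_expectancy = life_expectancy,
    gdp_per_capita = gdp_per_capita, the_per_capita = the_per_capita,
    ssnc_need_fraction = ssnc_need_fraction,
    mean_admission_days = mean_admission_days
  )
}

validate_interventions <- function(interventions) {
  check_columns(interventions,
                c("name", "cause", "effectiveness", "affected_fraction",
                  "baseline_coverage", "target_coverage"),
                "interventions")
  check_proportion(interventions$effectiveness, "effectiveness")
  check_proportion(interventions$affected_fraction, "affected_fraction")
  check_proportion(interventions$baseline_coverage, "baseline_coverage")
  check_proportion(interventions$target_coverage, "target_coverage")
  if (any(interventions$target_coverage < interventions$baseline_coverage)) {
    stop_invalid("target_coverage must be >= baseline_coverage for every intervention")
  }
  if (anyDuplicated(interventions$name)) {
    stop_invalid("intervention names must be unique")
  }
  invisible(interventions)
}

validate_cause_shares <- function(cause_shares) {
  check_columns(cause_shares, c("cause", "share_of_deaths"), "cause_shares")
  check_proportion(cause_shares$share_of_deaths, "share_of_deaths")
  if (abs(sum(cause_shares$share_of_deaths) - 1) > 1e-9) {
    stop_invalid("cause shares must sum to 1 (got ",
                 format(sum(cause_shares$share_of_deaths), digits = 12), ")")
  }
  invisible(cause_shares)
}

#' Build a coverage scale-up trajectory
#'
#' Interpolates intervention coverage from a baseline value in the start year
#' to a target value in the end year. Only linear interpolation is currently
#' offered; the shape argument is an extension point.
#'
#' @param baseline,target Coverage proportions in `[0, 1]`, `target >= baseline`.
#' @param start_year,end_year Calendar years, `end_year > start_year`.
#' @param shape Interpolation shape; only `"linear"`.
#'
#' @return A tibble with columns `year` and `coverage`, non-decreasing, with
#'   endpoints equal to `baseline` and `target`.
#' @examples
#' build_trajectory(0.10, 0.85, 2021, 2025)
#' @export
build_trajectory <- function(baseline, target, start_year, end_year,
                             shape = c("linear")) {
  shape <- match.arg(shape)
  check_proportion(baseline, "baseline")
  check_proportion(target, "target")
  if (target < baseline) stop_invalid("target coverage must be >= baseline coverage")
  if (end_year <= start_year) stop_invalid("end_year must be > start_year")
  years <- seq(start_year, end_year)
  coverage <- baseline + (target - baseline) *
    (years - start_year) / (end_year - start_year)
  tibble::tibble(year = years, coverage = coverage)
}

#' Proportional mortality reduction for one cause of death
#'
#' Converts coverage gains of the interventions acting on a single cause into
#' the proportion of that cause's baseline deaths averted. Each intervention
#' removes `effectiveness x affected_fraction x coverage` of the deaths left by
#' the previous one (a residual product), so combining interventions never
#' double counts: the reduction is
#' `1 - prod(1 - e_i a_i c_i(t)) / prod(1 - e_i a_i c_i(t0))`, clipped to
#' `[0, 1)`.
#'
#' @param interventions Data frame with columns `effectiveness` and
#'   `affected_fraction` (and optionally `cause`, which must then be a single
#'   value) describing the interventions acting on the cause.
#' @param coverage Coverage of each intervention at the evaluation time
#'   (recycled if length 1).
#' @param coverage_baseline Coverage at baseline; defaults to the
#'   `baseline_coverage` column of `interventions`.
#'
#' @return A single proportion in `[0, 1)`.
#' @examples
#' one <- tibble::tibble(effectiveness = 0.9, affected_fraction = 1)
#' cause_mortality_reduction(one, coverage = 0.85, coverage_baseline = 0.10)
#' @export
cause_mortality_reduction <- function(interventions, coverage,
                                      coverage_baseline = NULL) {
  check_columns(interventions, c("effectiveness", "affected_fraction"),
                "interventions")
  if ("cause" %in% names(interventions) &&
      length(unique(interventions$cause)) > 1L) {
    stop_invalid("all interventions must act on a single cause")
  }
  n <- nrow(interventions)
  if (is.null(coverage_baseline)) {
    check_columns(interventions, "baseline_coverage", "interventions")
    coverage_baseline <- interventions$baseline_coverage
  }
  coverage <- rep_len(coverage, n)
  coverage_baseline <- rep_len(coverage_baseline, n)
  check_proportion(coverage, "coverage")
  check_proportion(coverage_baseline, "coverage_baseline")
  impact_t <- interventions$effectiveness * interventions$affected_fraction * coverage
  impact_0 <- interventions$effectiveness * interventions$affected_fraction *
    coverage_baseline
  if (any(impact_t >= 1) || any(impact_0 >= 1)) {
    stop_invalid("effectiveness x affected_fraction x coverage must be < 1 ",
                 "(residual mortality cannot be negative)")
  }
  reduction <- 1 - prod(1 - impact_t) / prod(1 - impact_0)
  min(max(reduction, 0), 1 - .Machine$double.eps)
}

#' Project neonatal deaths and lives saved under coverage scale-up
#'
#' Deterministic cohort projection: baseline-year neonatal deaths (births x
#' NMR / 1000) are split across causes of death, each cause's deaths are
#' reduced according to [cause_mortality_reduction()] at that year's coverage,
#' and annual deaths averted are accumulated into cumulative lives saved.
#' Births and baseline cause-specific deaths are held constant over the
#' horizon (no secular trend).
#'
#' @param profile A [country_profile()].
#' @param interventions Intervention table: `name`, `cause`, `effectiveness`,
#'   `affected_fraction`, `baseline_coverage`, `target_coverage`.
#' @param cause_shares Data frame with `cause` and `share_of_deaths` summing
#'   to 1; every intervention's cause must appear here.
#' @param start_year First (baseline) year of scale-up.
#' @param horizon Last projected year.
#' @param trajectories Optional named list of coverage trajectories (as from
#'   [build_trajectory()]), one per intervention name. By default each
#'   intervention's coverage ramps linearly from its `baseline_coverage` in
#'   `start_year` to its `target_coverage` in `horizon`.
#'
#' @return An object of class `ssnc_impact`: use [tidy()] for the per-year
#'   projection (`year`, `deaths`, `deaths_averted`, `cumulative_lives_saved`,
#'   `nmr`), [glance()] for a one-row summary, and `$by_cause` for the split
#'   of cumulative lives saved across causes.
#' @examples
#' tz <- tanzania_fixture()
#' proj <- project_impact(tz$profile, tz$interventions, tz$cause_shares,
#'                        start_year = 2021, horizon = 2030)
#' glance(proj)
#' @export
project_impact <- function(profile, interventions, cause_shares,
                           start_year = 2021, horizon = 2030,
                           trajectories = NULL) {
  check_columns(profile, c("annual_births", "baseline_nmr"), "profile")
  validate_interventions(interventions)
  validate_cause_shares(cause_shares)
  missing_causes <- setdiff(interventions$cause, cause_shares$cause)
  if (length(missing_causes)) {
    stop_invalid("intervention cause(s) missing from cause_shares: ",
                 paste(missing_causes, collapse = ", "))
  }
  if (horizon <= start_year) stop_invalid("horizon must be > start_year")

  years <- seq(start_year, horizon)
  n_years <- length(years)
  if (is.null(trajectories)) {
    # linear ramp from baseline to target coverage over the horizon
    frac <- (years - start_year) / (horizon - start_year)
    cov_mat <- outer(frac, interventions$target_coverage -
                       interventions$baseline_coverage) +
      rep(interventions$baseline_coverage, each = n_years)
  } else {
    missing_traj <- setdiff(interventions$name, names(trajectories))
    if (length(missing_traj)) {
      stop_invalid("missing trajectories for: ", paste(missing_traj, collapse = ", "))
    }
    cov_mat <- vapply(interventions$name, function(nm) {
      tr <- trajectories[[nm]]
      check_columns(tr, c("year", "coverage"), paste0("trajectory for ", nm))
      out <- tr$coverage[match(years, tr$year)]
      if (anyNA(out)) {
        # hold coverage flat after a trajectory's end year (e.g. a 2025 ramp
        # evaluated to a 2030 horizon), but never before its start
        if (any(years < min(tr$year))) {
          stop_invalid("trajectory for ", nm, " starts after ", start_year)
        }
        out <- tr$coverage[findInterval(years, tr$year)]
      }
      out
    }, numeric(n_years))
  }

  baseline_deaths <- profile$annual_births * profile$baseline_nmr / 1000
  deaths_by_cause <- baseline_deaths * cause_shares$share_of_deaths

  # per-cause proportional reduction, residual-product form, vectorised
  # over years: 1 - prod_i(1 - e_i a_i c_i(t)) / prod_i(1 - e_i a_i c_i(t0))
  ea <- interventions$effectiveness * interventions$affected_fraction
  impact_mat <- cov_mat * rep(ea, each = n_years)
  impact_base <- ea * interventions$baseline_coverage
  if (any(impact_mat >= 1) || any(impact_base >= 1)) {
    stop_invalid("effectiveness x affected_fraction x coverage must be < 1 ",
                 "(residual mortality cannot be negative)")
  }
  averted_mat <- vapply(seq_along(cause_shares$cause), function(ci) {
    idx <- which(interventions$cause == cause_shares$cause[ci])
    if (!length(idx)) return(rep(0, n_years))
    residual_t <- exp(rowSums(log(1 - impact_mat[, idx, drop = FALSE])))
    residual_0 <- prod(1 - impact_base[idx])
    reduction <- pmin(pmax(1 - residual_t / residual_0, 0),
                      1 - .Machine$double.eps)
    deaths_by_cause[ci] * reduction
  }, numeric(n_years))

  annual_averted <- rowSums(averted_mat)
  deaths <- baseline_deaths - annual_averted
  data <- fast_tibble(
    year = years,
    deaths = deaths,
    deaths_averted = annual_averted,
    cumulative_lives_saved = cumsum(annual_averted),
    nmr = deaths / profile$annual_births * 1000
  )
  cause_totals <- colSums(averted_mat)
  by_cause <- fast_tibble(
    cause = cause_shares$cause,
    lives_saved = unname(cause_totals),
    share = if (sum(cause_totals) > 0) {
      unname(cause_totals) / sum(cause_totals)
    } else {
      rep(0, length(cause_totals))
    }
  )
  structure(
    list(
      data = data,
      by_cause = by_cause,
      baseline_deaths = baseline_deaths,
      start_year = start_year,
      horizon = horizon,
      annual_births = profile$annual_births,
      baseline_nmr = profile$baseline_nmr
    ),
    class = "ssnc_impact"
  )
}

#' Fraction of baseline deaths averted in a given year
#'
#' @param projection An `ssnc_impact` object from [project_impact()].
#' @param year A year inside the projection horizon.
#' @return Deaths averted in `year` divided by baseline annual deaths.
#' @export
percent_deaths_averted <- function(projection, year) {
  stopifnot(inherits(projection, "ssnc_impact"))
  row <- match(year, projection$data$year)
  if (is.na(row)) {
    stop_invalid("year ", year, " is outside the projection (",
                 projection$start_year, "-", projection$horizon, ")",
                 class = "ssnc_range")
  }
  projection$data$deaths_averted[row] / projection$baseline_deaths
}

#' Halve intervention effectiveness except for exempt interventions
#'
#' Models a lower-quality-of-care scenario in which high-impact interventions
#' operate at half effectiveness while named low-impact supportive
#' interventions keep theirs.
#'
#' @param interventions Intervention table.
#' @param exempt Character vector of intervention names left unchanged.
#' @return The intervention table with non-exempt `effectiveness` halved; all
#'   other fields identical.
#' @export
halve_effectiveness <- function(interventions, exempt = character()) {
  validate_interventions(interventions)
  unknown <- setdiff(exempt, interventions$name)
  if (length(unknown)) {
    stop_invalid("exempt name(s) not in interventions: ",
                 paste(unknown, collapse = ", "))
  }
  dplyr::mutate(
    interventions,
    effectiveness = ifelse(.data$name %in% exempt,
                           .data$effectiveness, .data$effectiveness * 0.5)
  )
}

# methods ---------------------------------------------------------------------

#' @export
print.ssnc_impact <- function(x, ...) {
  cat("SSNC impact projection ", x$start_year, "-", x$horizon, "\n", sep = "")
  cat("  baseline deaths/year: ", format(round(x$baseline_deaths), big.mark = ","),
      " (NMR ", x$baseline_nmr, ")\n", sep = "")
  final <- x$data[nrow(x$data), ]
  cat("  cumulative lives saved by ", x$horizon, ": ",
      format(round(final$cumulative_lives_saved), big.mark = ","), "\n", sep = "")
  cat("  NMR in ", x$horizon, ": ", round(final$nmr, 1),
      " per 1000 live births\n", sep = "")
  invisible(x)
}

#' @rdname project_impact
#' @param x An `ssnc_impact` object.
#' @param ... Unused.
#' @method tidy ssnc_impact
#' @export
tidy.ssnc_impact <- function(x, ...) x$data

#' @rdname project_impact
#' @method glance ssnc_impact
#' @export
glance.ssnc_impact <- function(x, ...) {
  final <- x$data[nrow(x$data), ]
  tibble::tibble(
    start_year = x$start_year,
    horizon = x$horizon,
    baseline_deaths = x$baseline_deaths,
    cumulative_lives_saved = final$cumulative_lives_saved,
    final_nmr = final$nmr,
    percent_deaths_averted = final$deaths_averted / x$baseline_deaths
  )
}

#' @rdname project_impact
#' @param object An `ssnc_impact` object.
#' @method autoplot ssnc_impact
#' @export
autoplot.ssnc_impact <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$data,
    c("nmr", "cumulative_lives_saved"),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(
    long$series,
    levels = c("nmr", "cumulative_lives_saved"),
    labels = c("NMR (per 1000 live births)", "Cumulative lives saved")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Projected impact of SSNC scale-up") +
    ggplot2::theme_minimal()
}
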