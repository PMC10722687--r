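# Activity-based incremental costing of level-2 newborn units.
#
# Setup costs (infrastructure, ward furniture & fixtures, neonatal devices)
# are one-off capital outlays annualised with a capital-recovery (annuity)
# factor. Running costs (human resources, supplies & consumables, medicines,
# data & quality improvement, maintenance) recur annually. Scenario A builds
# everything new; scenario B renovates half the structures at 20% of new-build
# cost and acquires half of the items.

#' Scenario rules for scale-up costing
#'
#' @param name `"A"` (all units and items new) or `"B"` (half new / half
#'   renovated structures, half of items acquired, reduced staffing table).
#' @return A one-row tibble with `name`, `new_fraction`,
#'   `renovation_cost_fraction` and `item_acquisition_fraction`.
#' @export
scenario_spec <- function(name = c("A", "B")) {
  name <- match.arg(name)
  if (name == "A") {
    fast_tibble(name = "A", new_fraction = 1.0,
                renovation_cost_fraction = 0.2,
                item_acquisition_fraction = 1.0)
  } else {
    fast_tibble(name = "B", new_fraction = 0.5,
                renovation_cost_fraction = 0.2,
                item_acquisition_fraction = 0.5)
  }
}

#' Cross-cutting costing rules
#'
#' @param discount_rate Annual discount rate used to annualise capital assets.
#' @param markup_consumables Mark-up applied to medical supplies and device
#'   consumables over the economic order quantity.
#' @param maintenance_rate Annual maintenance charge as a proportion of total
#'   setup cost.
#' @return A one-row tibble of the three rules.
#' @export
cost_rules <- function(discount_rate = 0.03, markup_consumables = 0.10,
                       maintenance_rate = 0.03) {
  check_number(discount_rate, "discount_rate", lower = 0)
  check_number(markup_consumables, "markup_consumables", lower = 0)
  check_number(maintenance_rate, "maintenance_rate", lower = 0)
  fast_tibble(discount_rate = discount_rate,
              markup_consumables = markup_consumables,
              maintenance_rate = maintenance_rate)
}

resolve_scenario <- function(scenario, bundle = NULL) {
  if (is.character(scenario) && length(scenario) == 1L) {
    if (!is.null(bundle) && !is.null(bundle$scenarios)) {
      row <- bundle$scenarios[bundle$scenarios$name == scenario, , drop = FALSE]
      if (nrow(row) == 1L) return(row)
    }
    return(scenario_spec(scenario))
  }
  check_columns(scenario, c("name", "new_fraction", "item_acquisition_fraction"),
                "scenario")
  if (is.null(scenario$renovation_cost_fraction)) {
    scenario$renovation_cost_fraction <- 0
  }
  scenario
}

#' Annuity (capital recovery) factor
#'
#' Present value of an annuity of 1 per year for `years` years at `rate`:
#' `(1 - (1 + rate)^-years) / rate`, with the zero-rate limit equal to
#' `years`. Dividing a one-off capital cost by this factor spreads it over
#' the asset's useful life as an equivalent annual cost.
#'
#' @param rate Annual discount rate (>= 0).
#' @param years Useful life in years (>= 1). Vectorised over both arguments.
#' @return The annuity factor.
#' @examples
#' annuity_factor(0.03, 20)
#' @export
annuity_factor <- function(rate, years) {
  if (any(years < 1)) stop_invalid("years must be >= 1")
  if (any(rate < 0)) stop_invalid("rate must be >= 0")
  n <- max(length(rate), length(years))
  rate <- rep_len(rate, n)
  years <- rep_len(years, n)
  out <- (1 - (1 + rate)^-years) / rate
  out[rate == 0] <- years[rate == 0]
  out
}

#' Equivalent annual cost of a one-off capital outlay
#'
#' @param one_off One-off cost in USD (>= 0).
#' @inheritParams annuity_factor
#' @return USD per year over the asset's useful life.
#' @examples
#' equivalent_annual_cost(358000, 0.03, 20)
#' @export
equivalent_annual_cost <- function(one_off, rate, years) {
  if (any(one_off < 0)) stop_invalid("one_off must be >= 0")
  one_off / annuity_factor(rate, years)
}

new_breakdown <- function(per_category, kind, level, scenario_name) {
  out <- per_category[order(per_category$category), ]
  structure(out,
            class = c("ssnc_breakdown", class(tibble::tibble())),
            kind = kind, level = level, scenario = scenario_name)
}

#' Total and annualised total of a cost breakdown
#'
#' @param breakdown A breakdown tibble from [setup_cost()] or [running_cost()].
#' @return `cost_total()`: the sum of category costs (USD);
#'   `cost_annualised_total()`: the sum of equivalent annual costs (USD/year,
#'   identical to the total for running costs).
#' @export
cost_total <- function(breakdown) sum(breakdown$cost)

#' @rdname cost_total
#' @export
cost_annualised_total <- function(breakdown) sum(breakdown$annualised)

#' Per-hospital setup cost under a scale-up scenario
#'
#' Expected one-off cost of establishing one newborn unit at the given
#' hospital level. Under scenario B the infrastructure cost is a blend of new
#' build and renovation, `unit_cost x (new_fraction + (1 - new_fraction) x
#' renovation_cost_fraction)`, and non-infrastructure items are scaled by the
#' item acquisition fraction. Capital categories are annualised at the rules'
#' discount rate over each item's useful life.
#'
#' @param catalogue Cost catalogue with columns `item`, `category`, `kind`,
#'   `level`, `unit_cost_usd`, `quantity`, `useful_life_years`.
#' @param level Hospital level, e.g. `"district"` or `"regional"`.
#' @param scenario Scenario name (`"A"`/`"B"`) or a [scenario_spec()] row.
#' @param rules A [cost_rules()] row.
#' @return A breakdown tibble (class `ssnc_breakdown`) with columns
#'   `category`, `cost`, `annualised`; see [cost_total()].
#' @examples
#' tz <- tanzania_fixture()
#' setup_cost(tz$catalogue, "district", "A", tz$cost_rules)
#' @export
setup_cost <- function(catalogue, level, scenario, rules = cost_rules()) {
  check_columns(catalogue,
                c("item", "category", "kind", "level", "unit_cost_usd",
                  "quantity", "useful_life_years"),
                "catalogue")
  scenario <- resolve_scenario(scenario)
  items <- catalogue[catalogue$kind == "setup" & catalogue$level == level, ]
  required <- c("infrastructure", "furniture_fixtures", "devices")
  missing <- setdiff(required, items$category)
  if (length(missing)) {
    stop_invalid("setup catalogue for level '", level, "' is missing: ",
                 paste(missing, collapse = ", "))
  }
  if (any(items$unit_cost_usd < 0) || any(items$quantity < 0)) {
    stop_invalid("unit costs and quantities must be >= 0")
  }
  if (any(is.na(items$useful_life_years)) || any(items$useful_life_years <= 0)) {
    stop_invalid("setup items need a positive useful_life_years")
  }
  infra_scale <- scenario$new_fraction +
    (1 - scenario$new_fraction) * scenario$renovation_cost_fraction
  scale <- ifelse(items$category == "infrastructure",
                  infra_scale, scenario$item_acquisition_fraction)
  cost <- items$unit_cost_usd * items$quantity * scale
  annualised <- cost / annuity_factor(rules$discount_rate,
                                      items$useful_life_years)
  agg <- rowsum(cbind(cost = cost, annualised = annualised),
                group = items$category)
  per_category <- fast_tibble(category = rownames(agg),
                              cost = unname(agg[, "cost"]),
                              annualised = unname(agg[, "annualised"]))
  new_breakdown(per_category, "setup", level, scenario$name)
}

#' Annual staffing cost for one hospital
#'
#' Incremental ward staffing is a policy table: headcounts per cadre are read
#' for the given level and scenario and multiplied by 12 monthly salaries.
#'
#' @param staffing Staffing table with columns `cadre`, `level`, `scenario`,
#'   `count`, `monthly_salary_usd`. "Not charged" cadres are rows with
#'   count 0 (or simply absent).
#' @param level Hospital level.
#' @param scenario Scenario name or [scenario_spec()] row.
#' @return Annual human-resources cost in USD for one hospital.
#' @export
staffing_cost <- function(staffing, level, scenario) {
  check_columns(staffing,
                c("cadre", "level", "scenario", "count", "monthly_salary_usd"),
                "staffing")
  scenario <- resolve_scenario(scenario)
  rows <- staffing[staffing$level == level & staffing$scenario == scenario$name, ]
  if (any(rows$monthly_salary_usd < 0)) stop_invalid("salaries must be >= 0")
  if (any(rows$count < 0)) stop_invalid("staff counts must be >= 0")
  sum(rows$count * 12 * rows$monthly_salary_usd)
}

#' Staff headcount from a coverage ratio (reference helper)
#'
#' Derives a round-the-clock ward headcount from a staff-to-cot ratio:
#' `ceiling(cots / ratio x shifts x uplift)`, where `uplift` covers leave and
#' maternity cover. Provided for planning what-ifs; the packaged Tanzania
#' staffing table uses the government's printed headcounts directly, which
#' this formula does not reproduce.
#'
#' @param cots Ward cot capacity.
#' @param ratio Cots per staff member on shift (e.g. 4 for a 1:4 ratio).
#' @param shifts Shifts per day (default 3 for 8-hour shifts).
#' @param uplift Multiplier for leave and maternity cover.
#' @return Integer headcount.
#' @export
staff_from_ratio <- function(cots, ratio, shifts = 3, uplift = 1.15) {
  check_number(cots, "cots", lower = 0, strict_lower = TRUE)
  check_number(ratio, "ratio", lower = 0, strict_lower = TRUE)
  as.integer(ceiling(cots / ratio * shifts * uplift))
}

#' Per-hospital annual running cost under a scale-up scenario
#'
#' Combines human resources (from the staffing policy table), medical supplies
#' and device consumables (with the rules' mark-up over the economic order
#' quantity), neonatal medicines, data & quality-improvement systems, and
#' maintenance charged as a proportion of the setup cost. Under scenario B,
#' catalogue items are scaled by the item acquisition fraction and staffing is
#' read from the scenario B policy table.
#'
#' @inheritParams setup_cost
#' @param staffing Staffing policy table (see [staffing_cost()]).
#' @param setup The setup breakdown from [setup_cost()] for the same level and
#'   scenario; maintenance is `maintenance_rate x cost_total(setup)`.
#' @return A breakdown tibble (class `ssnc_breakdown`); running categories
#'   pass through annualisation unchanged.
#' @examples
#' tz <- tanzania_fixture()
#' s <- setup_cost(tz$catalogue, "district", "A", tz$cost_rules)
#' running_cost(tz$catalogue, tz$staffing, "district", "A", tz$cost_rules, s)
#' @export
running_cost <- function(catalogue, staffing, level, scenario,
                         rules = cost_rules(), setup) {
  scenario <- resolve_scenario(scenario)
  items <- catalogue[catalogue$kind == "running" & catalogue$level == level, ]
  if (any(items$unit_cost_usd < 0) || any(items$quantity < 0)) {
    stop_invalid("unit costs and quantities must be >= 0")
  }
  markup <- ifelse(items$category == "supplies_consumables",
                   1 + rules$markup_consumables, 1)
  cost <- items$unit_cost_usd * items$quantity * markup *
    scenario$item_acquisition_fraction
  agg <- rowsum(cost, group = items$category)
  per_category <- fast_tibble(
    category = c(rownames(agg), "human_resources", "maintenance"),
    cost = c(unname(agg[, 1]),
             staffing_cost(staffing, level, scenario),
             rules$maintenance_rate * cost_total(setup))
  )
  per_category$annualised <- per_category$cost
  new_breakdown(per_category, "running", level, scenario$name)
}

#' National roll-out of setup and running costs
#'
#' Computes per-hospital setup and running cost breakdowns for every hospital
#' level in the roll-out plan and scales them by hospital counts into
#' per-level and national totals.
#'
#' @param bundle A configuration bundle (see [tanzania_fixture()] /
#'   [generate_bundle()]) containing `catalogue`, `staffing`, `rollout`,
#'   `cost_rules` and `scenarios`.
#' @param scenario Scenario name (`"A"` or `"B"`) or a [scenario_spec()] row.
#' @return An object of class `ssnc_costs` with elements
#'   `per_hospital` (category-level breakdown per level), `by_level`
#'   (per-level totals and per-hospital annualised totals) and `national`
#'   (one-row national totals). [tidy()] returns the category breakdown,
#'   [glance()] the national summary row.
#' @examples
#' tz <- tanzania_fixture()
#' glance(national_rollout(tz, "A"))
#' @export
national_rollout <- function(bundle, scenario = "A") {
  scenario <- resolve_scenario(scenario, bundle)
  rules <- bundle$cost_rules
  check_columns(bundle$rollout, c("level", "bed_capacity", "n_hospitals"),
                "rollout")
  if (any(bundle$rollout$n_hospitals < 0)) {
    stop_invalid("hospital counts must be >= 0")
  }

  per_level <- purrr::map(seq_len(nrow(bundle$rollout)), function(i) {
    level <- bundle$rollout$level[i]
    n <- bundle$rollout$n_hospitals[i]
    setup <- setup_cost(bundle$catalogue, level, scenario, rules)
    running <- running_cost(bundle$catalogue, bundle$staffing, level, scenario,
                            rules, setup)
    n_rows <- nrow(setup) + nrow(running)
    per_hospital <- fast_tibble(
      level = rep(level, n_rows),
      kind = rep(c("setup", "running"), c(nrow(setup), nrow(running))),
      category = c(setup$category, running$category),
      cost = c(setup$cost, running$cost),
      annualised = c(setup$annualised, running$annualised)
    )
    list(
      per_hospital = per_hospital,
      summary = fast_tibble(
        level = level,
        n_hospitals = n,
        setup_per_hospital = cost_total(setup),
        setup_annualised_per_hospital = cost_annualised_total(setup),
        running_per_hospital = cost_total(running),
        annualised_total_per_hospital =
          cost_annualised_total(setup) + cost_total(running),
        setup_total = n * cost_total(setup),
        setup_annualised = n * cost_annualised_total(setup),
        running_annual = n * cost_total(running),
        annual_total = n * (cost_annualised_total(setup) + cost_total(running))
      )
    )
  })

  by_level <- dplyr::bind_rows(purrr::map(per_level, "summary"))
  national <- fast_tibble(
    n_hospitals = sum(by_level$n_hospitals),
    setup_total = sum(by_level$setup_total),
    setup_annualised = sum(by_level$setup_annualised),
    running_annual = sum(by_level$running_annual),
    annual_total = sum(by_level$annual_total)
  )
  structure(
    list(
      per_hospital = dplyr::bind_rows(purrr::map(per_level, "per_hospital")),
      by_level = by_level,
      national = national,
      scenario = scenario$name
    ),
    class = "ssnc_costs"
  )
}

#' @export
print.ssnc_costs <- function(x, ...) {
  cat("SSNC national roll-out costs, scenario ", x$scenario, "\n", sep = "")
  cat("  hospitals: ", x$national$n_hospitals, "\n", sep = "")
  cat("  one-off setup:     US$", format(round(x$national$setup_total),
                                         big.mark = ","), "\n", sep = "")
  cat("  annualised setup:  US$", format(round(x$national$setup_annualised),
                                         big.mark = ","), "/year\n", sep = "")
  cat("  annual running:    US$", format(round(x$national$running_annual),
                                         big.mark = ","), "/year\n", sep = "")
  cat("  total annualised:  US$", format(round(x$national$annual_total),
                                         big.mark = ","), "/year\n", sep = "")
  invisible(x)
}

#' @rdname national_rollout
#' @param x,object An `ssnc_costs` object.
#' @param ... Unused.
#' @method tidy ssnc_costs
#' @export
tidy.ssnc_costs <- function(x, ...) x$per_hospital

#' @rdname national_rollout
#' @method glance ssnc_costs
#' @export
glance.ssnc_costs <- function(x, ...) {
  dplyr::mutate(x$national, scenario = x$scenario, .before = 1)
}

#' @rdname national_rollout
#' @method autoplot ssnc_costs
#' @export
autoplot.ssnc_costs <- function(object, ...) {
  ggplot2::ggplot(
    object$per_hospital,
    ggplot2::aes(x = .data$level, y = .data$cost, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::scale_y_continuous(labels = function(v) format(v, big.mark = ",")) +
    ggplot2::labs(x = NULL, y = "US$ per hospital",
                  title = paste0("Per-hospital incremental costs (scenario ",
                                 object$scenario, ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
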