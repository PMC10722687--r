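# Configuration bundles: the unit of input for the whole pipeline.
#
# A bundle is a list of validated tibbles (country profile, monetisation and
# costing rules, scenario rules, cause-of-death shares, intervention table,
# roll-out plan, cost catalogue, staffing table, implementation schedule)
# plus a country label and base year. Bundles round-trip to a directory of
# CSV files, one YAML config, and a hash manifest.

bundle_csv_parts <- c("interventions", "cause_shares", "rollout", "catalogue",
                      "staffing", "schedule")

new_bundle <- function(parts) {
  structure(parts, class = "ssnc_bundle")
}

#' @export
print.ssnc_bundle <- function(x, ...) {
  cat("SSNC configuration bundle: ", x$country, " (base year ", x$base_year,
      ")\n", sep = "")
  cat("  ", nrow(x$interventions), " interventions across ",
      length(unique(x$interventions$cause)), " causes; ",
      nrow(x$cause_shares), " cause shares\n", sep = "")
  cat("  roll-out: ",
      paste(sprintf("%d %s hospitals", x$rollout$n_hospitals, x$rollout$level),
            collapse = ", "), "\n", sep = "")
  cat("  catalogue: ", nrow(x$catalogue), " line items; staffing: ",
      nrow(x$staffing), " rows; schedule ", min(x$schedule$year), "-",
      max(x$schedule$year), "\n", sep = "")
  invisible(x)
}

#' Validate a configuration bundle
#'
#' Checks every structural invariant of a bundle: positive demography, cause
#' shares on the simplex, coverage bounds and ordering, non-negative costs
#' and useful lives, staffing counts, schedule monotonicity, and that every
#' intervention cause and catalogue level is resolvable.
#'
#' @param bundle A configuration bundle.
#' @param collect If `TRUE`, return a character vector of problems (empty when
#'   valid) instead of erroring.
#' @return Invisibly `TRUE` when valid; with `collect = TRUE`, the problem
#'   list. Otherwise errors with all failed invariants.
#' @export
validate_bundle <- function(bundle, collect = FALSE) {
  problems <- character()
  note <- function(cond) problems <<- c(problems, conditionMessage(cond))
  try_check <- function(expr) tryCatch(expr, error = note)

  required <- c("country", "base_year", "profile", "monetisation", "cost_rules",
                "scenarios", "cause_shares", "interventions", "rollout",
                "catalogue", "staffing", "schedule")
  missing <- setdiff(required, names(bundle))
  if (length(missing)) {
    problems <- c(problems,
                  paste0("bundle is missing parts: ",
                         paste(missing, collapse = ", ")))
  } else {
    try_check(do.call(country_profile, as.list(bundle$profile)))
    try_check(validate_interventions(bundle$interventions))
    try_check(validate_cause_shares(bundle$cause_shares))
    try_check({
      bad <- setdiff(bundle$interventions$cause, bundle$cause_shares$cause)
      if (length(bad)) {
        stop_invalid("intervention cause(s) missing from cause_shares: ",
                     paste(bad, collapse = ", "))
      }
    })
    try_check(validate_schedule(bundle$schedule))
    try_check({
      check_columns(bundle$rollout, c("level", "bed_capacity", "n_hospitals"),
                    "rollout")
      if (any(bundle$rollout$bed_capacity <= 0)) {
        stop_invalid("bed_capacity must be > 0")
      }
      if (any(bundle$rollout$n_hospitals < 0)) {
        stop_invalid("n_hospitals must be >= 0")
      }
    })
    for (sc in c("A", "B")) {
      for (lv in bundle$rollout$level) {
        try_check(setup_cost(bundle$catalogue, lv, sc, bundle$cost_rules))
        try_check(staffing_cost(bundle$staffing, lv, sc))
      }
    }
  }
  if (collect) return(problems)
  if (length(problems)) {
    rlang::abort(
      paste0("invalid bundle:\n",
             paste0("  - ", problems, collapse = "\n")),
      class = "ssnc_invalid_bundle"
    )
  }
  invisible(TRUE)
}

#' Write a configuration bundle to a directory
#'
#' Writes one CSV per tabular part, a `country.yml` with the scalar
#' configuration, and a `manifest.json` listing every file with its MD5
#' content hash.
#'
#' @param bundle A configuration bundle.
#' @param dir Target directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    interventions = bundle$interventions,
    cause_shares = bundle$cause_shares,
    rollout = bundle$rollout,
    cost_catalogue = bundle$catalogue,
    staffing = bundle$staffing,
    schedule = bundle$schedule
  )
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  config <- list(
    country = bundle$country,
    base_year = bundle$base_year,
    profile = as.list(bundle$profile),
    monetisation = as.list(bundle$monetisation),
    cost_rules = as.list(bundle$cost_rules),
    scenarios = lapply(seq_len(nrow(bundle$scenarios)), function(i) {
      as.list(bundle$scenarios[i, ])
    })
  )
  yaml::write_yaml(config, file.path(dir, "country.yml"),
                   precision = 15L)
  files <- sort(c(paste0(names(tables), ".csv"), "country.yml"))
  manifest <- list(
    files = lapply(files, function(f) {
      list(file = f, md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a configuration bundle from a directory
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand in
#'   the same layout).
#' @param check Validate the bundle after reading (default `TRUE`).
#' @return A configuration bundle.
#' @export
read_bundle <- function(dir, check = TRUE) {
  if (!dir.exists(dir)) stop_invalid("bundle directory does not exist: ", dir)
  need <- c("country.yml", "interventions.csv", "cause_shares.csv",
            "rollout.csv", "cost_catalogue.csv", "staffing.csv", "schedule.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop_invalid("bundle directory is missing: ", paste(missing, collapse = ", "))
  }
  config <- yaml::read_yaml(file.path(dir, "country.yml"))
  read_part <- function(name, col_types) {
    readr::read_csv(file.path(dir, paste0(name, ".csv")),
                    col_types = col_types, progress = FALSE)
  }
  bundle <- new_bundle(list(
    country = config$country,
    base_year = as.integer(config$base_year),
    profile = tibble::as_tibble(config$profile),
    monetisation = tibble::as_tibble(config$monetisation),
    cost_rules = tibble::as_tibble(config$cost_rules),
    scenarios = dplyr::bind_rows(lapply(config$scenarios, tibble::as_tibble)),
    interventions = read_part("interventions", "ccdddd"),
    cause_shares = read_part("cause_shares", "cd"),
    rollout = read_part("rollout", "cdi"),
    catalogue = read_part("cost_catalogue", "ccccddd"),
    staffing = read_part("staffing", "cccdd"),
    schedule = read_part("schedule", "id")
  ))
  if (check) validate_bundle(bundle)
  bundle
}

#' The packaged Tanzania configuration
#'
#' The worked national example shipped with the package: 2.15 million annual
#' births at a baseline NMR of 20, six SSNC interventions, a roll-out of 146
#' district and 25 regional referral hospitals with their setup and running
#' cost catalogues, the incremental staffing tables for both scenarios, the
#' 2021-2030 gradual implementation schedule, and monetisation constants
#' (GDP per capita US$1,099, multiplier 2.3, statistical life-year US$2,401).
#' Cause-of-death shares are calibrated so that the projection reproduces the
#' published cumulative lives saved and their split across causes; the
#' calibration derivation ships with the package sources
#' (`tools/calibrate-cause-shares.R`).
#'
#' @return A configuration bundle.
#' @examples
#' tz <- tanzania_fixture()
#' tz$interventions
#' @export
tanzania_fixture <- function() {
  read_bundle(system.file("extdata", "tanzania", package = "ssncinvest"))
}

# synthetic bundles -----------------------------------------------------------

#' Default generator ranges for synthetic bundles
#'
#' Each element is a `c(min, max)` pair. The defaults span plausible
#' low- and middle-income country configurations around the packaged worked
#' example: national birth cohorts from hundreds of thousands to a few
#' million, NMRs between 5 and 40 per 1000, and hospital unit costs spanning
#' an order of magnitude either side of the Tanzanian catalogue.
#'
#' @return A named list of range pairs.
#' @export
default_ranges <- function() {
  list(
    annual_births = c(2e5, 5e6),
    population_per_birth = c(20, 40),
    baseline_nmr = c(5, 40),
    life_expectancy = c(50, 80),
    gdp_per_capita = c(400, 8000),
    the_per_capita = c(15, 300),
    effectiveness = c(0.05, 0.95),
    affected_fraction = c(0.3, 1),
    baseline_coverage = c(0, 0.3),
    target_coverage = c(0.4, 0.95),
    infrastructure_cost = c(1e5, 3e6),
    furniture_cost = c(1e4, 2e5),
    device_cost = c(1e4, 5e5),
    running_item_cost = c(5e3, 2e5),
    monthly_salary = c(150, 1500),
    staff_count = c(1, 20),
    n_district = c(10, 200),
    n_regional = c(2, 50)
  )
}

check_ranges <- function(ranges) {
  defaults <- default_ranges()
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop_invalid("infeasible range for ", nm,
                   ": need an ordered c(min, max) pair")
    }
  }
  if (ranges$baseline_coverage[2] > ranges$target_coverage[1]) {
    # baselines above the lowest target are handled by drawing targets
    # above each baseline, but the ranges must still leave room
    if (ranges$baseline_coverage[2] >= ranges$target_coverage[2]) {
      stop_invalid("infeasible range: baseline_coverage cannot exceed target_coverage")
    }
  }
  ranges
}

runif_r <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate an internally consistent synthetic configuration bundle
#'
#' Draws a random country configuration (demography, causes of death,
#' interventions, hospital roll-out, cost catalogue, staffing tables,
#' implementation schedule) that satisfies every bundle invariant: coverage
#' targets at or above baselines, cause shares on the simplex, positive
#' costs, scenario-B staffing no larger than scenario A. Generation is fully
#' reproducible from the seed and leaves the caller's random-number state
#' untouched.
#'
#' @param seed Integer seed.
#' @param ranges Named list overriding entries of [default_ranges()]; a
#'   degenerate range (`min == max`) pins a field.
#' @param n_interventions_per_cause Range of interventions drawn for each
#'   intervention-bearing cause.
#' @return A configuration bundle.
#' @examples
#' b <- generate_bundle(1)
#' validate_bundle(b)
#' @export
generate_bundle <- function(seed, ranges = list(),
                            n_interventions_per_cause = c(1, 2)) {
  ranges <- check_ranges(ranges)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  births <- runif_r(1, ranges$annual_births)
  profile <- country_profile(
    population = births * runif_r(1, ranges$population_per_birth),
    annual_births = births,
    baseline_nmr = runif_r(1, ranges$baseline_nmr),
    life_expectancy = runif_r(1, ranges$life_expectancy),
    gdp_per_capita = runif_r(1, ranges$gdp_per_capita),
    the_per_capita = runif_r(1, ranges$the_per_capita),
    ssnc_need_fraction = stats::runif(1, 0.05, 0.2),
    mean_admission_days = stats::runif(1, 3, 14)
  )

  causes <- c("prematurity", "sepsis", "intrapartum", "congenital", "other")
  raw <- stats::runif(length(causes), 0.05, 1)
  cause_shares <- fast_tibble(cause = causes, share_of_deaths = raw / sum(raw))

  target_causes <- setdiff(causes, "other")
  n_each <- sample(seq(n_interventions_per_cause[1],
                       n_interventions_per_cause[2]),
                   length(target_causes), replace = TRUE)
  interventions <- dplyr::bind_rows(purrr::map2(target_causes, n_each, function(cs, k) {
    baseline <- runif_r(k, ranges$baseline_coverage)
    target <- pmax(baseline, runif_r(k, ranges$target_coverage))
    fast_tibble(
      name = paste0(cs, "_intervention_", seq_len(k)),
      cause = rep(cs, k),
      effectiveness = runif_r(k, ranges$effectiveness),
      affected_fraction = runif_r(k, ranges$affected_fraction),
      baseline_coverage = baseline,
      target_coverage = target
    )
  }))

  rollout <- fast_tibble(
    level = c("district", "regional"),
    bed_capacity = c(round(stats::runif(1, 20, 60)), round(stats::runif(1, 60, 120))),
    n_hospitals = as.integer(c(round(runif_r(1, ranges$n_district)),
                               round(runif_r(1, ranges$n_regional))))
  )

  make_catalogue <- function(level, scale) {
    fast_tibble(
      item = paste0(level, c("_newborn_unit_block", "_ward_furniture_set",
                             "_device_set", "_supplies_consumables",
                             "_neonatal_medicines", "_data_qi_system")),
      category = c("infrastructure", "furniture_fixtures", "devices",
                   "supplies_consumables", "medicines", "data_qi"),
      kind = c("setup", "setup", "setup", "running", "running", "running"),
      level = rep(level, 6),
      unit_cost_usd = c(runif_r(1, ranges$infrastructure_cost) * scale,
                        runif_r(1, ranges$furniture_cost) * scale,
                        runif_r(1, ranges$device_cost) * scale,
                        runif_r(3, ranges$running_item_cost) * scale),
      quantity = rep(1, 6),
      useful_life_years = c(20, 5, 5, NA, NA, NA)
    )
  }
  catalogue <- dplyr::bind_rows(make_catalogue("district", 1),
                                make_catalogue("regional", stats::runif(1, 1.5, 4)))

  cadres <- c("nurse", "medical_doctor", "nursing_assistant")
  salaries <- runif_r(length(cadres), ranges$monthly_salary)
  staffing <- dplyr::bind_rows(purrr::map(c("district", "regional"), function(lv) {
    count_a <- round(runif_r(length(cadres), ranges$staff_count))
    count_b <- ceiling(count_a / 2)
    k <- length(cadres)
    fast_tibble(cadre = rep(cadres, 2), level = rep(lv, 2 * k),
                scenario = rep(c("A", "B"), c(k, k)),
                count = c(count_a, count_b),
                monthly_salary_usd = rep(salaries, 2))
  }))

  base_year <- 2021L
  fractions <- sort(stats::runif(10, 0.05, 1))
  fractions[10] <- 1
  schedule <- fast_tibble(year = seq(base_year, base_year + 9L),
                          fraction = fractions)

  monetisation <- monetisation_spec(
    method = "gdp_multiplier",
    gdp_per_capita = profile$gdp_per_capita,
    gdp_multiplier = stats::runif(1, 1, 3),
    vsl_year = profile$gdp_per_capita * stats::runif(1, 1, 3),
    gdp_growth = 0.03, discount_rate = 0.03
  )

  bundle <- new_bundle(list(
    country = paste0("synthetic-", seed),
    base_year = base_year,
    profile = profile,
    monetisation = monetisation,
    cost_rules = cost_rules(),
    scenarios = dplyr::bind_rows(scenario_spec("A"), scenario_spec("B")),
    cause_shares = cause_shares,
    interventions = interventions,
    rollout = rollout,
    catalogue = catalogue,
    staffing = staffing,
    schedule = schedule
  ))
  validate_bundle(bundle)
  bundle
}
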