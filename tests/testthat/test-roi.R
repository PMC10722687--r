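test_that("capital stream is the annualised setup cost times the window length", {
  expect_equal(setup_stream(10731570, 10), 107315700)
  expect_equal(setup_stream(6128652, 10), 61286520)
  expect_equal(setup_stream(123456, 0), 0)
  expect_error(setup_stream(-1, 10), class = "ssnc_invalid")
})

tz_schedule <- tibble::tibble(
  year = 2021:2030,
  fraction = c(0.25, 0.30, 0.35, 0.40, 0.55, 0.60, 0.70, 0.85, 0.90, 1.00)
)

test_that("running stream follows the gradual implementation schedule", {
  rs <- running_stream(47e6, tz_schedule)
  expect_equal(rs$cost[rs$year == 2021], 11750000)
  expect_equal(sum(rs$cost), 277300000)
  full <- tibble::tibble(year = 2021:2030, fraction = rep(1, 10))
  expect_equal(sum(running_stream(47e6, full)$cost), 470000000)

  bad <- tz_schedule; bad$fraction[10] <- 0.9
  expect_error(running_stream(47e6, bad), class = "ssnc_invalid")
  bad2 <- tz_schedule; bad2$fraction[3] <- 0.1
  expect_error(running_stream(47e6, bad2), class = "ssnc_invalid")
})

test_that("npv uses end-of-year discounting from the base year", {
  rs <- running_stream(47e6, tz_schedule)
  expect_equal(npv(rs, 0), sum(rs$cost))
  one <- tibble::tibble(year = 2022, cost = 103)
  expect_equal(npv(one, 0.03, base_year = 2021), 100)
  # brute-force oracle: explicit per-year discount factors
  oracle <- sum(rs$cost / 1.03^(rs$year - 2021))
  expect_equal(npv(rs, 0.03, 2021), oracle, tolerance = 1e-12)
  # geometric closed form for a constant stream
  flat <- tibble::tibble(year = 2021:2030, cost = rep(5e6, 10))
  closed <- 5e6 * (1 - (1 / 1.03)^10) / (1 - 1 / 1.03)
  expect_equal(npv(flat, 0.03, 2021), closed, tolerance = 1e-9)
  # named-vector form agrees with the data-frame form
  expect_equal(npv(setNames(rs$cost, rs$year), 0.03, 2021),
               npv(rs, 0.03, 2021))
})

test_that("present value strictly decreases as the discount rate rises", {
  rs <- running_stream(47e6, tz_schedule)
  pvs <- vapply(c(0.01, 0.03, 0.08, 0.15), function(r) npv(rs, r, 2021),
                numeric(1))
  expect_true(all(diff(pvs) < 0))
  fvs <- vapply(c(0.01, 0.03, 0.08), function(r) {
    present_value_of_benefit(1e9, r, 66)
  }, numeric(1))
  expect_true(all(diff(fvs) < 0))
})

test_that("life-year valuation supports GDP-multiplier and VSL approaches", {
  gdp <- monetisation_spec("gdp_multiplier", gdp_per_capita = 1099,
                           gdp_multiplier = 2.3, vsl_year = 2401)
  expect_equal(value_per_life_year(gdp), 2527.7)
  vsl <- monetisation_spec("vsl", gdp_per_capita = 1099, vsl_year = 2401)
  expect_equal(value_per_life_year(vsl), 2401)
  unit <- monetisation_spec("gdp_multiplier", gdp_per_capita = 777,
                            gdp_multiplier = 1)
  expect_equal(value_per_life_year(unit), 777)
})

test_that("monetised benefits reproduce the worked national example", {
  m <- monetise_lives(80000, 66, 2401)
  expect_equal(m$yll, 5280000)
  expect_equal(m$future_value, 12677280000)
  m2 <- monetise_lives(80000, 66, 2527.7)
  expect_equal(m2$future_value, 13346256000)
  expect_equal(productivity_gains(80000, 46, 2527.7), 9301936000)
  expect_equal(productivity_gains(0, 46, 2527.7), 0)
  expect_equal(productivity_gains(1, 46, 2527.7), 116274.2)
})

test_that("lump-sum benefit discounting recovers the published present value", {
  expect_equal(present_value_of_benefit(13346256000, 0.03, 66),
               1897154151.13, tolerance = 0.005)
  expect_equal(present_value_of_benefit(5e9, 0, 66), 5e9)
  expect_equal(present_value_of_benefit(0, 0.03, 66), 0)
})

test_that("ROI is the ratio of discounted benefits to discounted costs", {
  expect_equal(compute_roi(376296700, 1897154151.13, 1250070111.94),
               (1897154151.13 + 1250070111.94) / 376296700)
  expect_equal(compute_roi(100, 60, 40), 1)
  expect_equal(compute_roi(100, 0, 0), 0)
  expect_error(compute_roi(0, 1, 1), class = "ssnc_invalid")
  # exact decomposition: roi x costs == social + productivity
  roi <- compute_roi(376296700, 1897154151.13, 1250070111.94)
  expect_equal(roi * 376296700, 1897154151.13 + 1250070111.94,
               tolerance = 1e-14)
})

test_that("budget impact divides annual cost by population, births and THE", {
  profile <- country_profile(61.5e6, 2.15e6, 20, 66, 1099, 40.62)
  b <- budget_impact(57e6, profile)
  expect_equal(b$cost_per_capita, 57e6 / 61.5e6)
  expect_equal(b$cost_per_birth, 57e6 / 2.15e6)
  expect_equal(b$share_of_the, (57e6 / 61.5e6) / 40.62)
  zero <- budget_impact(0, profile)
  expect_equal(unlist(zero), c(cost_per_capita = 0, cost_per_birth = 0,
                               share_of_the = 0))
})

test_that("full ROI analysis is internally consistent on the national example", {
  tz <- tz_bundle()
  roi <- roi_analysis(tz)
  s <- glance(roi)
  expect_equal(s$total_costs_pv,
               s$setup_costs_to_horizon + s$running_costs_to_horizon)
  expect_equal(s$roi_total * s$total_costs_pv,
               s$social_benefit_pv + s$productivity_pv, tolerance = 1e-12)
  expect_equal(s$cost_per_death_averted, s$total_costs_pv / s$lives_saved)
  expect_equal(s$yll_averted, s$lives_saved * 66)
  # every component is reported in the tidy worksheet
  td <- tidy(roi)
  expect_equal(td$value[td$component == "total ROI"], s$roi_total)
  expect_equal(nrow(td), 15)
  expect_s3_class(autoplot(roi), "ggplot")
})

test_that("monetary outputs scale with the currency and ROI is scale-free", {
  tz <- tz_bundle()
  k <- 3.7
  scaled <- tz
  scaled$catalogue$unit_cost_usd <- tz$catalogue$unit_cost_usd * k
  scaled$staffing$monthly_salary_usd <- tz$staffing$monthly_salary_usd * k
  scaled$profile$gdp_per_capita <- tz$profile$gdp_per_capita * k
  scaled$profile$the_per_capita <- tz$profile$the_per_capita * k
  scaled$monetisation$gdp_per_capita <- tz$monetisation$gdp_per_capita * k
  scaled$monetisation$vsl_year <- tz$monetisation$vsl_year * k

  base <- glance(roi_analysis(tz))
  up <- glance(roi_analysis(scaled))
  monetary <- c("setup_costs_to_horizon", "running_costs_to_horizon",
                "total_costs_pv", "social_benefit_fv", "social_benefit_pv",
                "productivity_fv", "productivity_pv", "cost_per_death_averted",
                "value_per_life_year")
  for (col in monetary) {
    expect_equal(up[[col]], k * base[[col]], tolerance = 1e-12)
  }
  expect_equal(up$roi_total, base$roi_total, tolerance = 1e-12)
  expect_equal(up$lives_saved, base$lives_saved)
  # budget share of THE is currency-free
  expect_equal(roi_analysis(scaled)$budget$share_of_the,
               roi_analysis(tz)$budget$share_of_the, tolerance = 1e-12)
})

test_that("sensitivity suite varies monetisation, running basis and care quality", {
  tz <- tz_bundle()
  sens <- sensitivity_suite(tz)
  cmp <- sens$comparison
  expect_equal(cmp$analysis,
               c("base", "vsl_monetisation", "coverage_running_costs"))
  # VSL life-year (2401) vs GDP approach (2527.7) future values
  expect_equal(cmp$social_benefit_fv[cmp$analysis == "base"] /
                 cmp$social_benefit_fv[cmp$analysis == "vsl_monetisation"],
               2527.7 / 2401, tolerance = 1e-9)
  # coverage-scaled running costs come in below the schedule-based stream
  expect_lt(cmp$total_costs_pv[3], cmp$total_costs_pv[1])
  # degraded quality of care saves far fewer lives over the 5-year window
  he <- sens$halved_effectiveness
  base_2025 <- glance(project_impact(tz$profile, tz$interventions,
                                     tz$cause_shares, 2021, 2025))
  expect_lt(he$cumulative_lives_saved, base_2025$cumulative_lives_saved)
  expect_gt(he$final_nmr, base_2025$final_nmr)
})
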