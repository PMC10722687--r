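test_that("annuity factor matches the explicit discount-factor sum", {
  # oracle: sum of 20 end-of-year discount factors at 3%
  expect_equal(annuity_factor(0.03, 20), sum(1 / 1.03^(1:20)),
               tolerance = 1e-12)
  expect_equal(annuity_factor(0.03, 20), 14.8775, tolerance = 1e-5)
  expect_equal(annuity_factor(0.03, 5), 4.5797, tolerance = 1e-4)
  expect_equal(annuity_factor(0, 5), 5)
  expect_equal(annuity_factor(0.03, c(20, 5)),
               c(annuity_factor(0.03, 20), annuity_factor(0.03, 5)))
  expect_error(annuity_factor(0.03, 0), class = "ssnc_invalid")
  expect_error(annuity_factor(-0.01, 5), class = "ssnc_invalid")
})

test_that("equivalent annual cost divides by the annuity factor and round-trips", {
  expect_equal(equivalent_annual_cost(358000, 0.03, 20),
               358000 / annuity_factor(0.03, 20))
  expect_equal(equivalent_annual_cost(358000, 0.03, 20), 24063.22,
               tolerance = 1e-6)
  expect_equal(equivalent_annual_cost(40000, 0.03, 5), 8734.18,
               tolerance = 1e-6)
  expect_equal(equivalent_annual_cost(0, 0.03, 7), 0)
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- runif(1, 0, 1e7); r <- runif(1, 0, 0.15); n <- sample(1:30, 1)
      expect_equal(equivalent_annual_cost(x, r, n) * annuity_factor(r, n), x,
                   tolerance = 1e-9)
    }
  })
})

test_that("district setup cost assembles the catalogue components per scenario", {
  tz <- tz_bundle()
  a <- setup_cost(tz$catalogue, "district", "A", tz$cost_rules)
  expect_equal(cost_total(a), 448000)
  expect_equal(a$cost[a$category == "infrastructure"], 358000)
  expect_equal(a$cost[a$category == "furniture_fixtures"], 50000)
  expect_equal(a$cost[a$category == "devices"], 40000)

  # scenario B blend: infrastructure at 0.5 + 0.5 x 0.2, items halved
  b <- setup_cost(tz$catalogue, "district", "B", tz$cost_rules)
  expect_equal(cost_total(b), 358000 * 0.6 + 90000 * 0.5)
  expect_equal(cost_total(b), 258000, tolerance = 0.01)

  zero <- dplyr::mutate(tz$catalogue, unit_cost_usd = 0)
  expect_equal(cost_total(setup_cost(zero, "district", "A", tz$cost_rules)), 0)

  gutted <- dplyr::filter(tz$catalogue, category != "devices")
  expect_error(setup_cost(gutted, "district", "A", tz$cost_rules),
               class = "ssnc_invalid")
})

test_that("staffing cost is headcount times twelve monthly salaries", {
  one <- tibble::tibble(cadre = "nurse", level = "district", scenario = "A",
                        count = 13, monthly_salary_usd = 420)
  expect_equal(staffing_cost(one, "district", "A"), 13 * 12 * 420)
  expect_equal(staffing_cost(one[0, ], "district", "A"), 0)

  tz <- tz_bundle()
  b_nurses <- dplyr::filter(tz$staffing, level == "district", scenario == "B",
                            cadre == "nurse")
  expect_equal(b_nurses$count, 7)
  expect_equal(staffing_cost(tz$staffing, "district", "B"),
               sum(dplyr::filter(tz$staffing, level == "district",
                                 scenario == "B")$count * 12 *
                     dplyr::filter(tz$staffing, level == "district",
                                   scenario == "B")$monthly_salary_usd))

  neg <- dplyr::mutate(one, monthly_salary_usd = -1)
  expect_error(staffing_cost(neg, "district", "A"), class = "ssnc_invalid")
})

test_that("running cost combines HR, marked-up supplies, and maintenance on setup", {
  tz <- tz_bundle()
  setup_a <- setup_cost(tz$catalogue, "district", "A", tz$cost_rules)
  run_a <- running_cost(tz$catalogue, tz$staffing, "district", "A",
                        tz$cost_rules, setup_a)
  expect_equal(cost_total(run_a), 231000)
  # maintenance charged at 3% of the 448,000 setup
  expect_equal(run_a$cost[run_a$category == "maintenance"], 0.03 * 448000)
  # 10% mark-up applies to supplies & consumables only
  supplies_base <- tz$catalogue$unit_cost_usd[
    tz$catalogue$category == "supplies_consumables" &
      tz$catalogue$level == "district"]
  expect_equal(run_a$cost[run_a$category == "supplies_consumables"],
               supplies_base * 1.1)
  medicines_base <- tz$catalogue$unit_cost_usd[
    tz$catalogue$category == "medicines" & tz$catalogue$level == "district"]
  expect_equal(run_a$cost[run_a$category == "medicines"], medicines_base)
  # running categories pass through annualisation unchanged
  expect_equal(run_a$annualised, run_a$cost)

  zero_cat <- dplyr::mutate(tz$catalogue, quantity = 0)
  zero_staff <- dplyr::mutate(tz$staffing, count = 0)
  zero_setup <- setup_cost(zero_cat, "district", "A", tz$cost_rules)
  expect_equal(cost_total(running_cost(zero_cat, zero_staff, "district", "A",
                                       tz$cost_rules, zero_setup)), 0)
})

test_that("national roll-out scales per-hospital costs by hospital counts", {
  tz <- tz_bundle()
  roll <- national_rollout(tz, "A")
  bl <- roll$by_level
  expect_equal(bl$setup_total, bl$n_hospitals * bl$setup_per_hospital)
  expect_equal(bl$annual_total,
               bl$n_hospitals * bl$annualised_total_per_hospital)
  expect_equal(roll$national$setup_total, sum(bl$setup_total))
  expect_equal(roll$national$annual_total, sum(bl$annual_total))
  expect_equal(bl$annualised_total_per_hospital,
               bl$setup_annualised_per_hospital + bl$running_per_hospital)

  none <- tz
  none$rollout$n_hospitals <- c(0L, 0L)
  empty <- national_rollout(none, "A")
  expect_equal(empty$national$setup_total, 0)
  expect_equal(empty$national$annual_total, 0)
})

test_that("cost-driver shares on the national example match the known structure", {
  tz <- tz_bundle()
  roll <- national_rollout(tz, "A")
  ph <- roll$per_hospital
  counts <- setNames(roll$by_level$n_hospitals, roll$by_level$level)
  ph$national <- ph$cost * counts[ph$level]

  setup <- ph[ph$kind == "setup", ]
  infra_share <- sum(setup$national[setup$category == "infrastructure"]) /
    sum(setup$national)
  expect_gte(infra_share, 0.80)
  expect_lte(infra_share, 0.86)

  running <- ph[ph$kind == "running", ]
  hr_share <- sum(running$national[running$category == "human_resources"]) /
    sum(running$national)
  expect_gte(hr_share, 0.55)
  expect_lte(hr_share, 0.65)

  # category shares partition each total
  expect_equal(sum(setup$national / sum(setup$national)), 1)
  expect_equal(sum(running$national / sum(running$national)), 1)
})

test_that("scenario B never costs more than scenario A", {
  tz <- tz_bundle()
  cmp <- compare_scenarios(tz)
  expect_true(all(cmp$delta >= 0))
  for (b in random_bundles(10, seed_offset = 700)) {
    cmp <- compare_scenarios(b)
    expect_true(all(cmp$delta >= -1e-9))
  }
})

test_that("ratio-based staffing helper reproduces shift arithmetic", {
  # 40 cots at 1:4 over three 8-hour shifts with 15% leave uplift
  expect_equal(staff_from_ratio(40, 4, shifts = 3, uplift = 1.15),
               ceiling(40 / 4 * 3 * 1.15))
  expect_error(staff_from_ratio(0, 4), class = "ssnc_invalid")
})
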