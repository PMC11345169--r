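test_that("throughput follows from test duration and effective hours", {
  cases <- list(
    list(minutes = 15, daily = 24, annual = 6240),
    list(minutes = 10, daily = 36, annual = 9360),
    list(minutes = 90, daily = 4, annual = 1040),
    list(minutes = 360, daily = 1, annual = 260) # one test fills the day
  )
  for (case in cases) {
    m <- screening_modality("x", case$minutes, cost_inventory())
    expect_identical(daily_throughput(m), as.integer(case$daily))
    expect_equal(annual_throughput(m), case$annual)
  }
  zero_cap <- screening_modality("slow", 24 * 60, cost_inventory(),
                                 effective_screening_hours_per_day = 6)
  expect_equal(daily_throughput(zero_cap), 0L)
  expect_equal(annual_throughput(zero_cap), 0)
  expect_error(screening_modality("bad", 0, cost_inventory()), "must be >")
  expect_error(screening_modality("bad", -5, cost_inventory()), "must be >")
})

test_that("equipment is annualized straight-line over its lifespan", {
  expect_equal(annualize_equipment(448416, 6), 74736)
  expect_equal(annualize_equipment(0, 6), 0)
  expect_equal(annualize_equipment(600, 6), 100)
  expect_error(annualize_equipment(100, 0), "lifespan")
  expect_error(annualize_equipment(-1, 6), "purchase_price")
})

test_that("staff costs are salary times apportioning statistic, and linear", {
  pediatrician <- staff_annual_cost(90000, 0.25)
  expect_equal(pediatrician$monthly_cost, 22500)
  expect_equal(pediatrician$annual_cost, 270000)
  expect_equal(staff_annual_cost(15000, 1)$annual_cost, 180000)
  expect_equal(staff_annual_cost(123456, 0)$annual_cost, 0)
  # linear in both salary and apportioning statistic
  base <- staff_annual_cost(20000, 0.4)$annual_cost
  expect_equal(staff_annual_cost(40000, 0.4)$annual_cost, 2 * base)
  expect_equal(staff_annual_cost(20000, 0.8)$annual_cost, 2 * base)
  expect_error(staff_annual_cost(1000, 1.2), "\\[0, 1\\]")
  # apportioning from screening hours: 2 h/day over 176 monthly hours
  expect_equal(apportioning_statistic(2), 0.25)
})

test_that("inventory totals are exact component sums", {
  expect_equal(total_annual_cost(paabr_inventory()), 602656)
  expect_equal(total_annual_cost(bera_inventory()), 1826181)
  expect_equal(total_annual_cost(cost_inventory()), 0)
  expect_error(cost_inventory(-1), ">= 0")
})

test_that("totals are permutation-invariant and additive under line splits", {
  set.seed(11)
  for (i in 1:20) {
    comps <- round(runif(6, 0, 1e6), 2)
    total <- total_annual_cost(do.call(cost_inventory, as.list(comps)))
    shuffled <- sample(comps)
    expect_equal(sum(shuffled), total)
    # splitting any component into two lines preserves the aggregated total
    lines <- tibble::tibble(
      modality = "m",
      category = c(rep("human_resource", 2), "medical_consumables",
                   "non_medical_consumables", "medical_equipment",
                   "non_medical_equipment", "overheads"),
      description = letters[1:7],
      amount = c(comps[1] * 0.3, comps[1] * 0.7, comps[2:6]),
      lifespan_years = NA_real_, monthly_salary = NA_real_,
      apportioning_statistic = NA_real_
    )
    lines$annual_cost <- lines$amount
    inv <- inventories_from_lines(lines)$m
    expect_equal(total_annual_cost(inv), total)
  }
})

test_that("unit cost divides total by throughput, rounding half-up on report", {
  uc <- unit_cost(paabr_modality())
  expect_equal(uc$unit_cost, 602656 / 6240)
  expect_equal(round(uc$unit_cost, 2), 96.58)
  expect_equal(uc$unit_cost_reported, 97)

  oae_printed <- screening_modality("OAE", 10, cost_inventory(622656))
  uc2 <- unit_cost(oae_printed)
  expect_equal(round(uc2$unit_cost, 2), 66.52)
  expect_equal(uc2$unit_cost_reported, 67)

  degenerate <- screening_modality("even", 90, cost_inventory(1040))
  expect_equal(unit_cost(degenerate)$unit_cost, 1)

  no_capacity <- screening_modality("none", 10, cost_inventory(100),
                                    working_days_per_year = 0)
  expect_error(unit_cost(no_capacity), "throughput")
})

test_that("reported and unrounded unit costs satisfy the rounding bound", {
  for (m in list(paabr_modality(), bera_modality())) {
    uc <- unit_cost(m)
    vol <- uc$annual_throughput
    expect_lt(abs(uc$unit_cost_reported * vol - uc$total_annual_cost),
              0.5 * vol)
    expect_equal(uc$unit_cost * vol, uc$total_annual_cost)
  }
})

test_that("the bundled cost inventory reproduces the reference totals", {
  csv <- system.file("extdata", "cost_inventory_2019_20.csv",
                     package = "hearcea")
  lines <- read_cost_inventory(csv)
  invs <- inventories_from_lines(lines)
  expect_setequal(names(invs), c("P-AABR", "OAE", "BERA"))
  expect_equal(total_annual_cost(invs[["P-AABR"]]), 602656)
  expect_equal(total_annual_cost(invs[["BERA"]]), 1826181)
  # the OAE component sum deliberately differs from the published 622,656
  expect_equal(total_annual_cost(invs[["OAE"]]), 622683)
  # staff lines aggregate into the human-resource component
  hr <- invs[["BERA"]]$human_resource
  expect_equal(hr, 600000 + 180000 + 216000 + 270000 + 25000)
})

test_that("cost inventory CSV is validated", {
  bad <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(modality = "x", category = "rent",
                                  description = "d", amount = 1,
                                  lifespan_years = NA, monthly_salary = NA,
                                  apportioning_statistic = NA), bad)
  expect_error(read_cost_inventory(bad), "unknown cost categories")
  bad2 <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(modality = "x", amount = 1), bad2)
  expect_error(read_cost_inventory(bad2), "lacks columns")
})
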