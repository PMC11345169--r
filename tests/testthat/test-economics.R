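test_that("lifetime QALYs weight detected and missed cases correctly", {
  co <- cohort_spec()
  all_detected <- expected_cascade(
    co, mode = cascade_mode("observed", referred = 500, confirmed = 262,
                            under_detected = 0)
  )
  expect_equal(strategy_qalys(co, all_detected, utility_weights()),
               100000 * 0.95 * 69.2) # 6,574,000
  empty <- cohort_spec(0)
  cc0 <- expected_cascade(empty, test_performance(1, 1))
  expect_equal(strategy_qalys(empty, cc0, utility_weights()), 0)
  # a single missed case accrues the hearing-loss utility over its lifetime
  one <- cohort_spec(1, 1000, 10)
  missed <- expected_cascade(one, mode = cascade_mode("observed", referred = 0,
                                                      confirmed = 0))
  expect_equal(strategy_qalys(one, missed, utility_weights()), 0.77 * 10)
})

test_that("QALYs are bounded above, with equality iff nothing is missed", {
  set.seed(3)
  for (i in 1:15) {
    co <- cohort_spec(sample(1000:50000, 1), runif(1, 0, 20))
    cc <- expected_cascade(co, test_performance(runif(1), runif(1)))
    q <- strategy_qalys(co, cc, utility_weights())
    upper <- co$size * 0.95 * co$life_expectancy_years
    expect_lte(q, upper + 1e-9)
    if (cc$under_detected == 0) expect_equal(q, upper)
    if (cc$under_detected > 0) expect_lt(q, upper)
  }
})

test_that("perspective costs: identity, OOPE additivity, monotonicity", {
  co <- cohort_spec()
  cc <- expected_cascade(co, test_performance(1, 0.97))
  free <- treatment_scenario("free_care", cost_per_treated_child = 0)
  hs <- strategy_total_cost("health_system", free, 5e6, cc)
  expect_equal(hs$total, 5e6) # identity with zero treatment cost

  no_oope <- oope_profile(wage_loss_per_visit = 0, visits_per_screened = 0,
                          visits_per_referred = 0)
  soc0 <- strategy_total_cost("societal", free, 5e6, cc, no_oope, co)
  expect_equal(soc0$total, hs$total)

  oope <- oope_profile()
  scen <- treatment_scenario("hearing_aid")
  hs1 <- strategy_total_cost("health_system", scen, 5e6, cc)
  soc1 <- strategy_total_cost("societal", scen, 5e6, cc, oope, co)
  expect_equal(soc1$total - hs1$total, expected_oope(co, cc, oope)$total)

  # detecting more cases never lowers health-system cost when treatment costs
  more <- expected_cascade(co, mode = cascade_mode("observed", referred = 3485,
                                                   confirmed = 400))
  fewer <- expected_cascade(co, mode = cascade_mode("observed", referred = 3485,
                                                    confirmed = 200))
  expect_gt(strategy_total_cost("health_system", scen, 5e6, more)$total,
            strategy_total_cost("health_system", scen, 5e6, fewer)$total)
})

test_that("derived treatment-cost defaults are exposed and overridable", {
  ci <- treatment_scenario("cochlear_implant")
  ha <- treatment_scenario("hearing_aid")
  expect_equal(round(ci$cost_per_treated_child, 2), 1229552.89)
  expect_equal(round(ha$cost_per_treated_child, 2), 699745.55)
  custom <- treatment_scenario("bone_anchored", cost_per_treated_child = 5e5)
  expect_equal(custom$cost_per_treated_child, 5e5)
  expect_error(treatment_scenario("unknown_device"), "no default")
})

test_that("ICER handles ratios, dominance and equivalence", {
  res <- icer(10535915, 7256198, 6574000, 6574000 - 33.67)
  expect_equal(round_half_up(res$icer, 2), 97407.69)
  expect_equal(res$status, "icer")

  diff <- icer(332678772.18, 39111934.20, 1, 0)
  expect_equal(diff$delta_cost, 293566837.98)

  dom <- icer(100, 50, 10, 10) # zero QALY gain, extra cost
  expect_equal(dom$status, "cost_minimization")
  expect_true(is.na(dom$icer))
  expect_equal(icer(50, 100, 20, 10)$status, "dominant")
  expect_equal(icer(100, 50, 10, 20)$status, "dominated")
  expect_equal(icer(5, 5, 3, 3)$status, "equivalent")
})

test_that("swapping strategies negates both deltas, preserving the ICER", {
  set.seed(21)
  for (i in 1:20) {
    costs <- runif(2, 1e6, 1e8)
    qalys <- runif(2, 1e5, 1e6)
    ab <- icer(costs[1], costs[2], qalys[1], qalys[2])
    ba <- icer(costs[2], costs[1], qalys[2], qalys[1])
    expect_equal(ba$delta_cost, -ab$delta_cost)
    expect_equal(ba$delta_qaly, -ab$delta_qaly)
    expect_equal(ba$icer, ab$icer)
  }
})

test_that("tidy() and glance() summarize a CEA result", {
  res <- icer(100, 60, 12, 10, label_a = "new", label_b = "old")
  td <- tidy(res)
  expect_equal(td$strategy, c("new", "old"))
  expect_equal(td$cost, c(100, 60))
  gl <- glance(res)
  expect_equal(gl$delta_cost, 40)
  expect_equal(gl$icer, 20)
})

test_that("cost per case detected is a guarded quotient", {
  expect_equal(cost_per_case_detected(1000, 10), 100)
  expect_equal(round(cost_per_case_detected(10535915, 262), 1), 40213.4)
  expect_equal(round(cost_per_case_detected(7256198, 26), 1), 279084.5)
  expect_error(cost_per_case_detected(1000, 0), "undefined")
})

test_that("one-way sweeps re-evaluate the pipeline on a grid", {
  cfg <- toy_config()
  # zero treatment cost: ICER reduces to screening-only increment per QALY
  zero <- set_config_parameter(cfg, "treatment_cost:hearing_aid", 0)
  sweep <- one_way_sensitivity(zero, "prevalence_per_1000", 2, 10, steps = 3)
  for (i in seq_len(nrow(sweep))) {
    cfg_i <- set_config_parameter(zero, "prevalence_per_1000", sweep$value[i])
    bundle <- run_pipeline(cfg_i)
    expect_equal(sweep$icer[i],
                 bundle$final_comparison$delta_screening_cost /
                   bundle$final_comparison$delta_qaly_model)
  }

  # doubling prevalence doubles detected cases and halves cost per case
  b1 <- run_pipeline(cfg)
  cfg2 <- set_config_parameter(cfg, "prevalence_per_1000", 10)
  b2 <- run_pipeline(cfg2)
  expect_equal(b2$strategy_summary$cases_detected,
               2 * b1$strategy_summary$cases_detected)
  expect_lt(b2$strategy_summary$cost_per_case_detected[1],
            b1$strategy_summary$cost_per_case_detected[1])

  # five-point sensitivity sweep is finite wherever the QALY delta is nonzero
  sens_sweep <- one_way_sensitivity(cfg, "sensitivity:A", 0.5, 1, steps = 5)
  expect_equal(nrow(sens_sweep), 5)
  expect_true(all(is.finite(sens_sweep$icer[sens_sweep$delta_qaly != 0])))

  expect_error(one_way_sensitivity(cfg, "not_a_parameter", 0, 1),
               "unknown parameter")
})
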