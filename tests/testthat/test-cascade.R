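test_that("sens_spec cascade follows the branch formulas", {
  cc <- expected_cascade(cohort_spec(), test_performance(1, 0.97))
  expect_equal(cc$screen_true_positive, 500)
  expect_equal(cc$screen_false_negative, 0)
  expect_equal(cc$screen_false_positive, 2985)
  expect_equal(cc$screen_true_negative, 96515)
  expect_equal(cc$referred, 3485)
  expect_equal(cc$confirmed_cases, 500)
  expect_equal(cc$under_detected, 0)
})

test_that("observed mode carries field detection rates through the cascade", {
  paabr <- expected_cascade(
    cohort_spec(),
    mode = cascade_mode("observed", referred = 500, confirmed = 262,
                        under_detected = 0)
  )
  expect_equal(paabr$confirmed_cases, 262)
  expect_equal(paabr$false_referrals, 238)
  expect_equal(paabr$confirmation_false_negative, 238)
  expect_equal(paabr$under_detected, 0)

  oae <- expected_cascade(
    cohort_spec(),
    mode = cascade_mode("observed", referred = 344, confirmed = 26,
                        under_detected = 3)
  )
  expect_equal(oae$confirmed_cases, 26)
  expect_equal(oae$false_referrals, 318)
  expect_equal(oae$under_detected, 3)

  # default under-detection: screen-level misses
  oae2 <- expected_cascade(
    cohort_spec(), mode = cascade_mode("observed", referred = 344, confirmed = 26)
  )
  expect_equal(oae2$under_detected, 500 - 344)
})

test_that("inconsistent observed inputs are rejected, not clamped", {
  expect_error(cascade_mode("observed", referred = 10, confirmed = 20),
               "cannot exceed")
  expect_error(cascade_mode("observed", referred = 10), "requires")
  expect_error(
    expected_cascade(cohort_spec(prevalence_per_1000 = 0),
                     mode = cascade_mode("observed", referred = 10,
                                         confirmed = 5)),
    "zero prevalence"
  )
  expect_error(
    expected_cascade(cohort_spec(),
                     mode = cascade_mode("observed", referred = 600,
                                         confirmed = 400,
                                         under_detected = 200)),
    "inconsistent"
  )
})

test_that("branch counts are conserved for arbitrary parameters", {
  set.seed(7)
  for (i in 1:25) {
    co <- cohort_spec(sample(1000:200000, 1), runif(1, 0, 50))
    perf <- test_performance(runif(1), runif(1))
    conf <- test_performance(runif(1, 0.5, 1), runif(1, 0.5, 1))
    cc <- expected_cascade(co, perf, conf)
    branches <- cc$screen_true_positive + cc$screen_false_negative +
      cc$screen_false_positive + cc$screen_true_negative
    expect_equal(branches, co$size)
    expect_equal(cc$screen_true_positive + cc$screen_false_negative,
                 co$diseased)
    expect_equal(cc$referred,
                 cc$screen_true_positive + cc$screen_false_positive)
    expect_lte(cc$confirmed_cases, cc$referred)
  }
})

test_that("a perfect test detects everyone at minimal referral volume", {
  co <- cohort_spec(50000, 8)
  cc <- expected_cascade(co, perfect_test())
  expect_equal(cc$referred, co$diseased)
  expect_equal(cc$confirmed_cases, co$diseased)
  expect_equal(cc$under_detected, 0)
  cost <- program_screening_cost(co, 10, 100, cc)
  expect_equal(cost$total, co$size * 10 + co$diseased * 100)
})

test_that("predictive values derive from the referral stream", {
  paabr <- expected_cascade(
    cohort_spec(), mode = cascade_mode("observed", referred = 500,
                                       confirmed = 262, under_detected = 0)
  )
  expect_equal(derived_ppv_npv(paabr)$ppv, 0.524)
  oae <- expected_cascade(
    cohort_spec(), mode = cascade_mode("observed", referred = 344,
                                       confirmed = 26, under_detected = 3)
  )
  expect_equal(round(derived_ppv_npv(oae)$ppv, 4), 0.0756)
  # no screen false negatives -> NPV 1
  cc <- expected_cascade(cohort_spec(), test_performance(1, 0.9))
  expect_equal(derived_ppv_npv(cc)$npv, 1)
  # undefined denominators error
  none_referred <- expected_cascade(cohort_spec(100, 0),
                                    test_performance(1, 1))
  expect_error(derived_ppv_npv(none_referred), "PPV undefined")
})

test_that("PPV rises with prevalence and equals it when sens = 1 - spec", {
  perf <- test_performance(0.8, 0.9)
  prev <- c(1, 5, 20, 100)
  ppvs <- vapply(prev, function(p) {
    derived_ppv_npv(expected_cascade(cohort_spec(100000, p), perf))$ppv
  }, numeric(1))
  expect_true(all(diff(ppvs) > 0))
  # uninformative test: referral rate independent of status -> PPV = prevalence
  uninformative <- test_performance(0.3, 0.7)
  cc <- expected_cascade(cohort_spec(100000, 50), uninformative)
  expect_equal(derived_ppv_npv(cc)$ppv, 0.05)
})

test_that("program cost decomposes over branches and handles edge cases", {
  co <- cohort_spec(1000, 100)
  cc <- expected_cascade(co, test_performance(1, 1))
  cost <- program_screening_cost(co, 10, 100, cc)
  expect_equal(cost$total, 20000) # 1000 x 10 + 100 x 100
  expect_equal(sum(cost$branches$cost), cost$total)
  empty <- program_screening_cost(
    cohort_spec(0), 10, 100,
    expected_cascade(cohort_spec(0), test_performance(1, 1))
  )
  expect_equal(empty$total, 0)
})

test_that("tidy() exposes per-branch counts with a rounded reporting view", {
  cc <- expected_cascade(cohort_spec(), test_performance(0.695, 0.683))
  tbl <- tidy(cc)
  expect_s3_class(tbl, "tbl_df")
  expect_setequal(tbl$branch[1:4], c("A", "B", "C", "D"))
  expect_equal(sum(tbl$expected[1:4]), 100000)
  expect_equal(tbl$reported, round_half_up(tbl$expected))
})
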