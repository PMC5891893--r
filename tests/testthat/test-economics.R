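test_that("discount factors follow (1 + r)^-cycle", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 10), 1.03^-10)
  expect_lt(abs(discount_factor(0.03, 1) - 0.97087), 5e-6)
  expect_lt(abs(discount_factor(0.03, 10) - 0.74409), 5e-6)
  expect_error(discount_factor(-0.01, 1), "non-negative")
  expect_error(discount_factor(0.03, -1), "non-negative")
})

test_that("QALY accumulation weights occupancy by utility", {
  # a cohort held in the cured state for one undiscounted cycle: 1 QALY
  mp <- toy_parameters(horizon = 1, recurrence = 0)
  tr <- run_cohort(mp, "self_care", init = c(0, 0, 0, 0, 1, 0))
  expect_equal(accumulate_qalys(tr, mp, rate = 0), 1)
  # held in dysmenorrhea instead: the dysmenorrhea utility
  mp2 <- toy_parameters(horizon = 1, cure_dys = 0, p12 = 0, vp_dys = 0)
  tr2 <- run_cohort(mp2, "self_care", init = c(0, 1, 0, 0, 0, 0))
  expect_equal(accumulate_qalys(tr2, mp2, rate = 0), 0.637)
  # discounting can only lose value; zero rate recovers the undiscounted sum
  mp3 <- model_parameters()
  tr3 <- run_cohort(mp3, "self_care")
  q_disc <- accumulate_qalys(tr3, mp3, rate = 0.03)
  q_undisc <- accumulate_qalys(tr3, mp3, rate = 0)
  expect_lt(q_disc, q_undisc)
  expect_lte(q_undisc, mp3$horizon)
})

test_that("an all-susceptible cohort accrues no cost in either perspective", {
  mp <- toy_parameters(incidence = 0, horizon = 5)
  cp <- cost_parameters()
  for (s in strategies()) {
    tr <- run_cohort(mp, s)
    expect_equal(as.numeric(accumulate_costs(tr, cp, "payer", mp = mp)), 0)
    expect_equal(as.numeric(accumulate_costs(tr, cp, "societal", mp = mp)), 0)
  }
})

test_that("surgery costing uses the complexity-weighted operation fee", {
  # one full person-year of surgery events
  expect_equal(0.452 * 456667 + (1 - 0.452) * 288080, 364281.324)
  mp <- toy_parameters(horizon = 1, surgery = 1, cure_endo12 = 0,
                       cure_endo34 = 0, vp_endo = 1, p34 = 0)
  cp <- cost_parameters()
  tr <- run_cohort(mp, "intervention", init = c(0, 0, 0, 1, 0, 0))
  expect_equal(sum(tr$events$surgery), 1)
  cost <- as.numeric(accumulate_costs(tr, cp, "payer", rate = 0, mp = mp))
  visit_part <- 4 * 11291  # the person-year also carries endometriosis visits
  expect_equal(cost - visit_part, 364281.324 + 207661)
})

test_that("payer costs never exceed societal costs", {
  res <- calibrated_base_case()
  for (arm in res$arms) {
    expect_lte(arm$cost_payer, arm$cost_societal)
    expect_lte(arm$cost_payer, arm$cost_payer_undisc)
  }
})

test_that("incremental comparison reproduces the published arithmetic identities", {
  a <- econ_from_totals("intervention", 326806, 1643076, 14.9)
  b <- econ_from_totals("self_care", 27758, 4768899, 12.3)
  ce <- compare_strategies(a, b, wtp = 5e6)
  expect_equal(ce$inc_cost, 299048)
  expect_equal(ce$inc_effect, 2.6)
  expect_equal(ce$icer, 299048 / 2.6)
  expect_lt(abs(ce$icer - 115018), 1)
  expect_true(ce$cost_effective)
  expect_equal(ce$smv, 4768899 - 1643076)
  expect_equal(ce$smv, 3125823)
  # SMV sign convention: positive iff the intervention's societal total is lower
  expect_gt(ce$smv, 0)
  ce_flip <- compare_strategies(b, a, wtp = 5e6)
  expect_lt(ce_flip$smv, 0)
})

test_that("identical arms yield zero increments and an undefined ICER", {
  a <- econ_from_totals("intervention", 1000, 2000, 10)
  ce <- compare_strategies(a, a)
  expect_equal(ce$inc_cost, 0)
  expect_true(is.na(ce$icer))
  expect_false(ce$cost_effective)
})
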