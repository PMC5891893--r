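test_that("one-way analysis perturbs only the named parameter", {
  params <- calibrated_base_case()$params
  # a societal-only cost has no pathway to the payer ICER
  e <- one_way(params, "selfmed_cost_annual", 10000, 20000, "icer")
  expect_equal(e$spread, 0)
  expect_false(e$non_monotone)
  # but it does move the societal incremental cost
  e2 <- one_way(params, "selfmed_cost_annual", 10000, 20000, "inc_cost")
  expect_gt(e2$spread, 0)
  e3 <- one_way(params, "discount_rate", 0.01, 0.05, "icer")
  expect_gt(e3$spread, 0)
  expect_error(one_way(params, "not_a_param", 0, 1, "icer"), "valid names")
  expect_error(one_way(params, "discount_rate", 0.05, 0.01, "icer"), "low < high")
})

test_that("tornado entries are sorted by spread and order-invariant", {
  params <- calibrated_base_case()$params
  ranges <- default_tornado_ranges("payer")[c(1, 4, 6), ]
  t1 <- tornado(params, ranges, "icer")
  expect_true(all(diff(t1$spread) <= 0))
  shuffled <- ranges[c(3, 1, 2), ]
  t2 <- tornado(params, shuffled, "icer")
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  # single range and empty ranges
  expect_equal(nrow(tornado(params, ranges[1, ], "icer")), 1)
  expect_equal(nrow(tornado(params, ranges[0, ], "icer")), 0)
  # degenerate ranges yield zero spreads
  deg <- data.frame(parameter = c("u_dys", "p_recurrence"),
                    low = c(0.637, 0.222), high = c(0.637, 0.222))
  expect_equal(tornado(params, deg, "icer")$spread, c(0, 0))
})

test_that("the full published tornado sets run and stay under the WTP threshold", {
  params <- calibrated_base_case()$params
  tp <- tornado(params, default_tornado_ranges("payer"), "icer")
  expect_equal(nrow(tp), 10)
  expect_true(all(c(tp$outcome_low, tp$outcome_high) > 0))
  expect_true(all(c(tp$outcome_low, tp$outcome_high) < 5e6))
  ts <- tornado(params, default_tornado_ranges("societal"), "inc_cost")
  expect_equal(nrow(ts), 7)
  # societal perspective: the discount rate is the most influential entry
  expect_equal(ts$parameter[1], "discount_rate")
  # risk-reduction OR endpoints keep the intervention cost-effective
  ow <- one_way(params, "or_develop_endo12", 0.2, 0.7, "icer")
  expect_true(all(c(ow$outcome_low, ow$outcome_high) < 5e6))
})

test_that("all-fixed distributions reproduce the base case exactly", {
  params <- calibrated_base_case()$params
  fixed <- lapply(params$distributions, function(d) {
    distribution_spec("fixed", d$central)
  })
  psa <- run_psa(params, fixed, n = 1, seed = 1)
  base_ce <- calibrated_base_case()$ce
  expect_equal(psa$draws$inc_cost, base_ce$inc_cost, tolerance = 1e-9)
  expect_equal(psa$draws$inc_effect, base_ce$inc_effect, tolerance = 1e-9)
})

test_that("PSA draws are reproducible and independent of the batch size", {
  params <- calibrated_base_case()$params
  p1 <- run_psa(params, n = 8, seed = 123)
  p2 <- run_psa(params, n = 8, seed = 123)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(params, n = 4, seed = 123)
  expect_identical(p3$draws, p1$draws[1:4, ])
  p4 <- run_psa(params, n = 8, seed = 124)
  expect_false(identical(p4$draws$inc_cost, p1$draws$inc_cost))
})

test_that("CEAC is a valid monotone acceptance curve", {
  params <- calibrated_base_case()$params
  psa <- run_psa(params, n = 60, seed = 5)
  cc <- ceac(psa)
  expect_true(all(cc$acceptance >= 0 & cc$acceptance <= 1))
  if (all(psa$draws$inc_effect > 0)) {
    expect_true(all(diff(cc$acceptance) >= 0))
  }
  # all-dominant draws accept everywhere
  dom <- structure(list(draws = data.frame(iteration = 1:3,
                                           inc_cost = c(-1, -2, -3),
                                           inc_effect = c(0.1, 0.2, 0.3)),
                        n = 3, seed = 1), class = "psa_result")
  expect_true(all(ceac(dom)$acceptance == 1))
})

test_that("PSA summaries behave on constant and known-normal draws", {
  const <- structure(list(draws = data.frame(iteration = 1:5,
                                             inc_cost = rep(100, 5),
                                             inc_effect = rep(1, 5)),
                          n = 5, seed = 1), class = "psa_result")
  s <- psa_summary(const)
  expect_equal(unname(s$inc_cost["p97.5"] - s$inc_cost["p2.5"]), 0)
  expect_equal(unname(s$inc_cost["sd"]), 0)
  # coverage of the normal-theory interval on synthetic normal draws
  set.seed(42)
  hits <- 0L
  for (i in 1:60) {
    x <- rnorm(400, mean = 10, sd = 2)
    p <- structure(list(draws = data.frame(iteration = seq_along(x),
                                           inc_cost = x, inc_effect = x),
                        n = length(x), seed = i), class = "psa_result")
    si <- psa_summary(p)
    q <- rnorm(1, 10, 2)  # a fresh draw from the truth
    hits <- hits + (q >= si$inc_cost["normal_low"] && q <= si$inc_cost["normal_high"])
  }
  expect_gt(hits / 60, 0.85)  # ~95% coverage, binomial slack
})

test_that("sampling respects parameter domains inside the pipeline", {
  params <- calibrated_base_case()$params
  set.seed(11)
  for (i in 1:25) {
    s <- sample_parameters(params)
    expect_true(s$values["or_develop_endo12"] <= 1)
    expect_true(all(s$values[c("u_dys", "u_endo12", "u_endo34")] <= 1))
    expect_true(s$values["prop_complex"] >= 0 && s$values["prop_complex"] <= 1)
  }
})

test_that("plot helpers return ggplot objects", {
  params <- calibrated_base_case()$params
  psa <- run_psa(params, n = 10, seed = 2)
  expect_s3_class(plot_ceac(ceac(psa)), "ggplot")
  tp <- tornado(params, default_tornado_ranges("payer")[1:3, ], "icer")
  expect_s3_class(plot_tornado(tp), "ggplot")
})
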