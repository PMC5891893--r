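test_that("the base case carries the published parameter values", {
  bc <- base_case_parameters()
  expect_equal(bc$model$p_progress_dys_to_endo12, 0.184)
  expect_equal(bc$model$p_recurrence, 0.222)
  expect_equal(bc$model$p_surgery_endo, 0.06)
  expect_equal(bc$model$prop_otc_selfcare, 0.871)
  expect_equal(bc$model$or_develop_endo12, 0.40)
  expect_equal(bc$model$or_progress_endo34, 0.10)  # reciprocal of the trial OR 10.00
  expect_equal(c(bc$model$u_dys, bc$model$u_endo12, bc$model$u_endo34,
                 bc$model$u_cured), c(0.637, 0.637, 0.549, 1.000))
  expect_equal(bc$model$discount_rate, 0.03)
  expect_equal(bc$model$start_age, 12)
  expect_equal(bc$model$horizon, 23)
  expect_equal(c(bc$model$cure_dys, bc$model$cure_endo12, bc$model$cure_endo34),
               c(0.80, 0.40, 0.80))
  # printed incidence and care-seeking ranges are the schedule extremes
  expect_equal(range(bc$model$incidence_dysmenorrhea$values), c(0.0008, 0.007))
  expect_equal(range(bc$model$visit_prop_dys$values), c(0.03, 0.5))
  expect_equal(range(bc$model$visit_prop_endo$values), c(0.0124, 0.0307))

  cp <- bc$cost
  expect_equal(cp$visit_cost_dys, 7529)
  expect_equal(cp$visit_cost_endo, 11291)
  expect_equal(cp$visits_per_year, 4)
  expect_equal(cp$inpatient_cost_annual, 207661)
  expect_equal(cp$surgery_cost_mild, 288080)
  expect_equal(cp$surgery_cost_complex, 456667)
  expect_equal(cp$prop_complex, 0.452)
  expect_equal(cp$otc_cost_annual, 19243)
  expect_equal(cp$selfmed_cost_annual, 13715)
  expect_equal(cp$productivity_loss_halfyear_selfcare, 184625)
  expect_equal(cp$productivity_loss_halfyear_intervention, 39546)
})

test_that("every uncertain parameter has a distribution of the published family", {
  bc <- base_case_parameters()
  d <- bc$distributions
  expect_equal(d$p_progress_dys_to_endo12$family, "beta")
  expect_equal(d$p_recurrence$family, "beta")
  expect_equal(d$p_surgery_endo$family, "normal")
  expect_equal(d$prop_otc_selfcare$family, "normal")
  expect_equal(d$or_develop_endo12$family, "lognormal")
  expect_equal(d$or_progress_endo34$family, "lognormal")
  for (nm in c("u_dys", "u_endo12", "u_endo34", "visit_cost_dys",
               "visit_cost_endo", "inpatient_cost_annual", "surgery_cost_mild",
               "surgery_cost_complex", "prop_complex", "otc_cost_annual",
               "selfmed_cost_annual", "productivity_loss_halfyear_selfcare",
               "productivity_loss_halfyear_intervention")) {
    expect_equal(d[[nm]]$family, "lognormal")
  }
  # distribution centres agree with the base-case values they describe
  for (nm in names(d)) {
    v <- bc$model[[nm]] %||% bc$cost[[nm]]
    expect_equal(d[[nm]]$central, v, info = nm)
  }
  # the calibration-adjusted assumptions are flagged calibratable
  expect_setequal(bc$calibratable,
                  c("cure_dys", "cure_endo12", "cure_endo34",
                    "p_progress_endo12_to_34"))
})

test_that("validation rejects out-of-domain parameters by name", {
  expect_error(model_parameters(u_dys = 1.2), "u_dys")
  expect_error(model_parameters(p_recurrence = -0.1), "p_recurrence")
  expect_error(model_parameters(or_develop_endo12 = 0), "or_develop_endo12")
  expect_error(model_parameters(horizon = 0), "horizon")
  expect_error(cost_parameters(visit_cost_dys = -1), "visit_cost_dys")
  expect_error(cost_parameters(prop_complex = 1.5), "prop_complex")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
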