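# Build self-consistent targets from a model's own self-care run.
targets_from_model <- function(mp, pop) {
  pc <- prevalence_counts(run_cohort(mp, "self_care"), pop)
  grp <- function(lo, hi) {
    mean(pc$by_age$prevalence[pc$by_age$age >= lo & pc$by_age$age <= hi])
  }
  data.frame(
    name = c("count", "p15", "p20", "p25", "p30"),
    kind = c("cumulative_count", rep("age_specific_prevalence", 4)),
    age_low = c(NA, 15, 20, 25, 30), age_high = c(NA, 19, 24, 29, 34),
    observed = c(pc$cumulative, grp(15, 19), grp(20, 24), grp(25, 29),
                 grp(30, 34)),
    weight = 1)
}

test_that("the objective vanishes at the generating parameters and grows away", {
  pop <- make_population()
  mp <- model_parameters(p_progress_endo12_to_34 = 0.3)
  targets <- targets_from_model(mp, pop)
  truth <- c(cure_dys = 0.80, cure_endo12 = 0.40, cure_endo34 = 0.80)
  expect_equal(calibration_objective(truth, targets, mp, pop = pop), 0)
  # perturbing any single healing rate strictly increases the objective
  for (nm in names(truth)) {
    for (delta in c(-0.1, 0.1)) {
      pert <- truth; pert[nm] <- pert[nm] + delta
      expect_gt(calibration_objective(pert, targets, mp, pop = pop), 0)
    }
  }
})

test_that("calibration recovers known healing rates from synthetic targets", {
  pop <- make_population()
  mp <- model_parameters(p_progress_endo12_to_34 = 0.3)
  targets <- targets_from_model(mp, pop)
  cal <- calibrate_model(targets,
                         free = c("cure_dys", "cure_endo12", "cure_endo34"),
                         mp = mp, pop = pop)
  expect_true(cal$converged)
  expect_lt(abs(cal$par["cure_dys"] - 0.80), 0.05)
  expect_lt(abs(cal$par["cure_endo12"] - 0.40), 0.05)
  expect_lt(abs(cal$par["cure_endo34"] - 0.80), 0.05)
})

test_that("calibration recovers the unprinted progression probability", {
  pop <- make_population()
  mp <- model_parameters(p_progress_endo12_to_34 = 0.27)
  targets <- targets_from_model(mp, pop)
  cal <- calibrate_model(targets, free = "p_progress_endo12_to_34",
                         mp = mp, pop = pop)
  expect_true(cal$converged)
  # recovery within the coarse-grid resolution
  expect_lt(abs(cal$par - 0.27), 0.02)
  expect_lt(cal$objective, 1e-6)
})

test_that("degenerate calibration inputs are rejected or flagged", {
  pop <- make_population()
  mp <- model_parameters()
  targets <- targets_from_model(mp, pop)
  targets$weight <- 0
  expect_error(calibrate_model(targets, mp = mp, pop = pop), "zero")
  expect_error(calibrate_model(targets_from_model(mp, pop),
                               bounds = list(p_progress_endo12_to_34 = c(0.4, 0.2)),
                               mp = mp, pop = pop), "infeasible")
  expect_error(calibration_objective(c(nonsense = 0.5),
                                     targets_from_model(mp, pop), mp, pop = pop),
               "unknown free parameter")
  # a monotone objective pushes a single free parameter to the boundary,
  # and the boundary is reported
  t2 <- targets_from_model(mp, pop)
  t2$observed[t2$kind == "cumulative_count"] <- 1  # unreachably small count
  t2$weight <- ifelse(t2$kind == "cumulative_count", 1, 0)
  cal <- calibrate_model(t2, free = "p_progress_endo12_to_34", mp = mp, pop = pop)
  expect_true(cal$at_boundary)
})

test_that("targets round-trip through their CSV schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(default_calibration_targets(), path, row.names = FALSE)
  t2 <- read_calibration_targets(path)
  expect_equal(t2$observed, default_calibration_targets()$observed)
  bad <- default_calibration_targets()
  bad$kind[1] <- "nonsense"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_calibration_targets(path), "kind")
})
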