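test_that("transition matrices are row-stochastic with the published entries", {
  mp <- model_parameters()
  for (s in strategies()) for (age in c(12, 20, 30, 34)) {
    M <- build_transition_matrix(mp, s, age)
    expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
  q <- mortality_at(mp$life_table, 20)
  # dysmenorrhea progression branch before competing adjustment
  M_sc <- build_transition_matrix(mp, "self_care", 20)
  expect_equal(M_sc["dys", "endo12"] / (1 - q), 0.184)
  M_iv <- build_transition_matrix(mp, "intervention", 20)
  expect_equal(M_iv["dys", "endo12"] / (1 - q),
               apply_odds_ratio(0.184, 0.40), tolerance = 1e-12)
  expect_lt(abs(M_iv["dys", "endo12"] / (1 - q) - 0.0781), 5e-5)
  # death is absorbing
  expect_equal(unname(M_sc["dead", ]), c(0, 0, 0, 0, 0, 1))
})

test_that("invalid branch probabilities raise construction errors", {
  mp <- toy_parameters(cure_endo34 = 0.98, surgery = 0.06, vp_endo = 1)
  expect_error(build_transition_matrix(mp, "intervention", 12), "endo34")
})

test_that("the cohort starts in the susceptible pool and conserves mass", {
  mp <- model_parameters()
  for (s in strategies()) {
    tr <- run_cohort(mp, s)
    expect_equal(unname(tr$occupancy[1, ]), c(1, 0, 0, 0, 0, 0))
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, mp$horizon + 1),
                 tolerance = 1e-12)
    expect_true(all(tr$occupancy >= 0))
    # death occupancy never decreases
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("degenerate cohorts behave as closed-form limits", {
  # no incidence: only the susceptible pool and deaths exist
  mp0 <- toy_parameters(incidence = 0, qx = 0.001)
  tr0 <- run_cohort(mp0, "self_care")
  expect_equal(rowSums(tr0$occupancy[, c("well", "dead")]),
               rep(1, mp0$horizon + 1), tolerance = 1e-12, ignore_attr = TRUE)
  # no mortality: the living mass stays 1
  mp1 <- toy_parameters(qx = 0)
  tr1 <- run_cohort(mp1, "intervention")
  expect_equal(rowSums(tr1$occupancy[, 1:5]), rep(1, mp1$horizon + 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("age-constant cohorts match the matrix-power oracle exactly", {
  mp <- toy_parameters(qx = 0.002, horizon = 8)
  for (s in strategies()) {
    M <- build_transition_matrix(mp, s, 12)
    tr <- run_cohort(mp, s)
    v <- c(1, 0, 0, 0, 0, 0)
    for (k in 1:8) {
      v <- as.vector(v %*% M)
      expect_equal(unname(tr$occupancy[k + 1, ]), v, tolerance = 1e-14)
    }
  }
})

test_that("endometriosis accounting matches hand-computed flows", {
  # one cycle, half the cohort in dysmenorrhea, no deaths:
  # expected new stage I/II entries = 0.5 * 0.184
  mp <- toy_parameters(horizon = 1, qx = 0)
  tr <- run_cohort(mp, "self_care", init = c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(sum(tr$events$entries_endo12), 0.092)
  expect_equal(cumulative_endometriosis(tr, "incidence"), 0.092)
  # zero progression: no endometriosis ever
  mp0 <- toy_parameters(p12 = 0, horizon = 5)
  tr0 <- run_cohort(mp0, "self_care")
  expect_equal(cumulative_endometriosis(tr0, "incidence"), 0)
  expect_equal(cumulative_endometriosis(tr0, "prevalence"), 0)
})

test_that("the intervention dominates self-care in endometriosis burden", {
  mp <- model_parameters()
  tr_sc <- run_cohort(mp, "self_care")
  tr_iv <- run_cohort(mp, "intervention")
  # cycle-wise dominance of cumulative entries and of point prevalence
  expect_true(all(cumsum(tr_iv$events$entries_endo12) <=
                    cumsum(tr_sc$events$entries_endo12) + 1e-15))
  prev <- function(tr) rowSums(tr$occupancy[, c("endo12", "endo34")])
  expect_true(all(prev(tr_iv) <= prev(tr_sc) + 1e-15))
})

test_that("prevalence scaling multiplies occupancy by population counts", {
  mp <- toy_parameters(horizon = 5)
  tr <- run_cohort(mp, "self_care")
  pop <- make_population(total = 3e7)
  pc <- prevalence_counts(tr, pop)
  expect_equal(pc$cumulative, sum(pc$by_age$cases))
  expect_equal(pc$by_age$cases,
               pc$by_age$prevalence * population_at(pop, pc$by_age$age))
  # missing age coverage errors
  small_pop <- make_population(data.frame(age_low = 12, age_high = 13), total = 1e6)
  expect_error(prevalence_counts(run_cohort(mp, "self_care"), small_pop),
               "not covered")
  # zero occupancy gives zero counts
  tr0 <- run_cohort(toy_parameters(incidence = 0, horizon = 5), "self_care")
  expect_equal(prevalence_counts(tr0, pop)$cumulative, 0)
})

test_that("the cohort engine agrees with a seeded microsimulation", {
  mp <- model_parameters()
  n <- 1e5
  for (s in strategies()) {
    occ_micro <- simulate_cohort_micro(mp, s, n = n, seed = 99)
    occ <- run_cohort(mp, s)$occupancy
    se <- sqrt(pmax(occ * (1 - occ), 1e-12) / n)
    # every state/cycle within 3 Monte-Carlo standard errors (plus a hair
    # of slack for states whose expected count is below ~1)
    expect_true(all(abs(occ_micro - occ) <= 3 * se + 3 / n))
  }
})
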