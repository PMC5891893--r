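# Shared fixtures for the test suite. Everything is built in code.

# A life table with constant annual mortality (handy for closed-form oracles).
flat_life_table <- function(qx = 0, ages = 0:80) {
  df <- data.frame(age = ages, qx = rep(qx, length(ages)))
  attr(df, "schedule") <- age_schedule(df$age, df$qx)
  class(df) <- c("life_table", "data.frame")
  df
}

# Age-constant toy parameters: every schedule flat, mortality constant, so the
# transition matrix is the same in every cycle and matrix powers are an oracle.
toy_parameters <- function(incidence = 0.05, cure_dys = 0.3, cure_endo12 = 0.2,
                           cure_endo34 = 0.4, p12 = 0.184, p34 = 0.3,
                           recurrence = 0.222, vp_dys = 1, vp_endo = 1,
                           qx = 0, horizon = 10, surgery = 0) {
  model_parameters(
    incidence_dysmenorrhea = age_schedule(12, incidence),
    p_progress_dys_to_endo12 = p12,
    cure_dys = cure_dys, cure_endo12 = cure_endo12, cure_endo34 = cure_endo34,
    p_recurrence = recurrence,
    visit_prop_dys = age_schedule(12, vp_dys),
    visit_prop_endo = age_schedule(12, vp_endo),
    p_surgery_endo = surgery,
    p_progress_endo12_to_34 = p34,
    life_table = flat_life_table(qx),
    horizon = horizon)
}

# Calibrated base-case parameter set, computed once per test session.
calibrated_base_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- run_base_case()
      cache <<- res
    }
    cache
  }
})

# Full-size PSA, computed once per test session (shared by the acceptance
# blocks so the 10,000 pipeline evaluations run only once).
psa_10k <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_psa(calibrated_base_case()$params, n = 10000,
                        seed = 20180410, keep_params = FALSE)
    }
    cache
  }
})

# Hand-built econ_result from printed arm totals (for arithmetic identities).
econ_from_totals <- function(strategy, cost_payer, cost_societal, qalys) {
  structure(list(strategy = strategy, cost_payer = cost_payer,
                 cost_societal = cost_societal, qalys = qalys,
                 components = c(direct_medical = cost_payer,
                                direct_nonmedical = 0,
                                opportunity = cost_societal - cost_payer)),
            class = "econ_result")
}
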