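#' @title Base-case epidemiological and effect parameters
#' @description
#' Constructor for the model parameter set: transition probabilities, effect
#' sizes, utilities and run settings for the yearly Markov cohort of women
#' followed from age 12 to 35.
#'
#' The three cure probabilities are annual remission probabilities *given
#' guideline-based treatment* (OC/progestin, or surgery for advanced
#' disease). The intervention arm receives treatment with certainty while
#' symptomatic; the self-care arm reaches treatment only through its
#' age-dependent care-seeking (visit-proportion) schedules, so its
#' effective remission is `visit_prop(age) * cure`. The intervention arm
#' additionally benefits from hazard-scale risk reductions on disease
#' development (`or_develop_endo12`) and progression (`or_progress_endo34`).
#'
#' `p_progress_endo12_to_34` (annual probability that untreated stage I/II
#' endometriosis advances to stage III/IV) is not observable from published
#' sources; its default is the value produced by the package's own
#' calibration against the shipped national prevalence targets (see
#' [calibrate_model()] and the methods vignette).
#'
#' @param incidence_dysmenorrhea,visit_prop_dys,visit_prop_endo
#'   [age_schedule()] objects (annual probabilities / proportions).
#' @param p_progress_dys_to_endo12 Annual probability that dysmenorrhea is
#'   complicated by stage I/II endometriosis.
#' @param cure_dys,cure_endo12,cure_endo34 Annual remission probabilities
#'   given treatment, by state.
#' @param p_recurrence Annual probability that a cured woman relapses to
#'   dysmenorrhea (both arms).
#' @param p_surgery_endo Annual probability of surgery among care-engaged
#'   endometriosis patients.
#' @param prop_otc_selfcare Proportion of self-care person-years using OTC
#'   analgesics (the remainder uses other self-medication).
#' @param or_develop_endo12,or_progress_endo34 Hazard-scale risk-reduction
#'   ratios active in the intervention arm.
#' @param p_progress_endo12_to_34 Annual untreated stage I/II to III/IV
#'   progression probability (calibrated).
#' @param u_well,u_dys,u_endo12,u_endo34,u_cured Utility weights in `[0,1]`.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param start_age Cohort entry age (years).
#' @param horizon Number of yearly cycles.
#' @param life_table A `life_table` for other-cause mortality.
#' @param maintenance_in_cured If `TRUE` (default), cured patients in the
#'   intervention arm stay on maintenance follow-up (visit costs and the
#'   reduced productivity loss continue).
#' @param surgery_to_cured If `TRUE` (default), surgery recipients move to
#'   the cured state in the same cycle; otherwise surgery is cost-only.
#' @return A validated `model_parameters` object (a list).
#' @export
model_parameters <- function(
    incidence_dysmenorrhea = age_schedule(c(12, 16, 30), c(0.0008, 0.007, 0.0008)),
    p_progress_dys_to_endo12 = 0.184,
    cure_dys = 0.80,
    cure_endo12 = 0.40,
    cure_endo34 = 0.80,
    p_recurrence = 0.222,
    visit_prop_dys = age_schedule(c(12, 30), c(0.03, 0.5)),
    visit_prop_endo = age_schedule(c(12, 30), c(0.0124, 0.0307)),
    p_surgery_endo = 0.06,
    prop_otc_selfcare = 0.871,
    or_develop_endo12 = 0.40,
    or_progress_endo34 = 0.10,
    p_progress_endo12_to_34 = 0.5,
    u_well = 1.0,
    u_dys = 0.637,
    u_endo12 = 0.637,
    u_endo34 = 0.549,
    u_cured = 1.0,
    discount_rate = 0.03,
    start_age = 12,
    horizon = 23,
    life_table = make_life_table(),
    maintenance_in_cured = TRUE,
    surgery_to_cured = TRUE) {
  mp <- list(
    incidence_dysmenorrhea = incidence_dysmenorrhea,
    p_progress_dys_to_endo12 = p_progress_dys_to_endo12,
    cure_dys = cure_dys, cure_endo12 = cure_endo12, cure_endo34 = cure_endo34,
    p_recurrence = p_recurrence,
    visit_prop_dys = visit_prop_dys, visit_prop_endo = visit_prop_endo,
    p_surgery_endo = p_surgery_endo,
    prop_otc_selfcare = prop_otc_selfcare,
    or_develop_endo12 = or_develop_endo12,
    or_progress_endo34 = or_progress_endo34,
    p_progress_endo12_to_34 = p_progress_endo12_to_34,
    u_well = u_well, u_dys = u_dys, u_endo12 = u_endo12,
    u_endo34 = u_endo34, u_cured = u_cured,
    discount_rate = discount_rate,
    start_age = start_age, horizon = horizon,
    life_table = life_table,
    maintenance_in_cured = isTRUE(maintenance_in_cured),
    surgery_to_cured = isTRUE(surgery_to_cured))
  class(mp) <- "model_parameters"
  validate_parameters(mp)
  mp
}

#' Base-case unit costs and resource-use parameters
#'
#' All monetary amounts are Japanese yen (JPY) at the model's price year;
#' `jpy_per_usd` (120) is display-only. Productivity losses are printed as
#' half-year amounts and annualised as twice the half-year value.
#'
#' @param visit_cost_dys,visit_cost_endo JPY per outpatient visit
#'   (drug-inclusive), by diagnosis.
#' @param visits_per_year Annual visit frequency while under care.
#' @param inpatient_cost_annual JPY per surgical admission year (excluding
#'   the surgery fee itself).
#' @param surgery_cost_mild,surgery_cost_complex JPY per operation.
#' @param prop_complex Proportion of operations that are complex.
#' @param otc_cost_annual,selfmed_cost_annual JPY per self-care person-year,
#'   split by the OTC-use proportion.
#' @param productivity_loss_halfyear_selfcare,productivity_loss_halfyear_intervention
#'   Opportunity cost per symptomatic (self-care) or managed (intervention)
#'   half-year.
#' @param jpy_per_usd Display-only exchange rate.
#' @return A validated `cost_parameters` object (a list).
#' @export
cost_parameters <- function(
    visit_cost_dys = 7529,
    visit_cost_endo = 11291,
    visits_per_year = 4,
    inpatient_cost_annual = 207661,
    surgery_cost_mild = 288080,
    surgery_cost_complex = 456667,
    prop_complex = 0.452,
    otc_cost_annual = 19243,
    selfmed_cost_annual = 13715,
    productivity_loss_halfyear_selfcare = 184625,
    productivity_loss_halfyear_intervention = 39546,
    jpy_per_usd = 120) {
  cp <- list(
    visit_cost_dys = visit_cost_dys, visit_cost_endo = visit_cost_endo,
    visits_per_year = visits_per_year,
    inpatient_cost_annual = inpatient_cost_annual,
    surgery_cost_mild = surgery_cost_mild,
    surgery_cost_complex = surgery_cost_complex,
    prop_complex = prop_complex,
    otc_cost_annual = otc_cost_annual,
    selfmed_cost_annual = selfmed_cost_annual,
    productivity_loss_halfyear_selfcare = productivity_loss_halfyear_selfcare,
    productivity_loss_halfyear_intervention = productivity_loss_halfyear_intervention,
    jpy_per_usd = jpy_per_usd)
  class(cp) <- "cost_parameters"
  validate_parameters(cp)
  cp
}

# Fields that must be probabilities / proportions in [0, 1].
.mp_prob_fields <- c("p_progress_dys_to_endo12", "cure_dys", "cure_endo12",
                     "cure_endo34", "p_recurrence", "p_surgery_endo",
                     "prop_otc_selfcare", "p_progress_endo12_to_34")
.mp_util_fields <- c("u_well", "u_dys", "u_endo12", "u_endo34", "u_cured")
.cp_cost_fields <- c("visit_cost_dys", "visit_cost_endo", "visits_per_year",
                     "inpatient_cost_annual", "surgery_cost_mild",
                     "surgery_cost_complex", "otc_cost_annual",
                     "selfmed_cost_annual", "productivity_loss_halfyear_selfcare",
                     "productivity_loss_halfyear_intervention")

#' Validate a parameter object
#'
#' Checks domain invariants (probabilities and utilities in `[0, 1]`, ratios
#' positive, costs non-negative, horizon at least one cycle) and errors with
#' the offending field name.
#'
#' @param x A `model_parameters` or `cost_parameters` object.
#' @return `x`, invisibly, if valid.
#' @export
validate_parameters <- function(x) {
  bad <- function(field, why) {
    stop(sprintf("invalid parameter `%s`: %s", field, why), call. = FALSE)
  }
  if (inherits(x, "model_parameters")) {
    for (f in .mp_prob_fields) {
      v <- x[[f]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
        bad(f, "must be a probability in [0, 1]")
    }
    for (f in .mp_util_fields) {
      v <- x[[f]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
        bad(f, "must be a utility weight in [0, 1]")
    }
    for (f in c("or_develop_endo12", "or_progress_endo34")) {
      if (!is.numeric(x[[f]]) || x[[f]] <= 0) bad(f, "must be a positive ratio")
    }
    for (f in c("incidence_dysmenorrhea", "visit_prop_dys", "visit_prop_endo")) {
      if (!inherits(x[[f]], "age_schedule")) bad(f, "must be an age_schedule")
    }
    if (x$discount_rate < 0) bad("discount_rate", "must be non-negative")
    if (!is.numeric(x$horizon) || x$horizon < 1) bad("horizon", "must be >= 1 cycle")
    if (!inherits(x$life_table, "life_table")) bad("life_table", "must be a life_table")
  } else if (inherits(x, "cost_parameters")) {
    for (f in .cp_cost_fields) {
      if (!is.numeric(x[[f]]) || x[[f]] < 0) bad(f, "must be a non-negative amount")
    }
    if (x$prop_complex < 0 || x$prop_complex > 1)
      bad("prop_complex", "must be a proportion in [0, 1]")
  } else {
    stop("validate_parameters(): unknown parameter object", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  cohort: start age %d, %d yearly cycles, discount %.1f%%\n",
              x$start_age, x$horizon, 100 * x$discount_rate))
  cat(sprintf("  dys -> endo I/II %.3f | cure (dys, I/II, III/IV) %.2f/%.2f/%.2f | recurrence %.3f\n",
              x$p_progress_dys_to_endo12, x$cure_dys, x$cure_endo12,
              x$cure_endo34, x$p_recurrence))
  cat(sprintf("  endo I/II -> III/IV %.3f (calibrated) | OR develop %.2f | OR progress %.2f\n",
              x$p_progress_endo12_to_34, x$or_develop_endo12, x$or_progress_endo34))
  cat(sprintf("  utilities (well/dys/I-II/III-IV/cured): %.3f/%.3f/%.3f/%.3f/%.3f\n",
              x$u_well, x$u_dys, x$u_endo12, x$u_endo34, x$u_cured))
  invisible(x)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("<cost_parameters> (JPY)\n")
  cat(sprintf("  visit: dys %s, endo %s x %d/yr | surgery mild %s / complex %s (%.1f%% complex)\n",
              format(x$visit_cost_dys, big.mark = ","),
              format(x$visit_cost_endo, big.mark = ","), x$visits_per_year,
              format(x$surgery_cost_mild, big.mark = ","),
              format(x$surgery_cost_complex, big.mark = ","), 100 * x$prop_complex))
  cat(sprintf("  inpatient/adm-yr %s | OTC %s | self-med %s\n",
              format(x$inpatient_cost_annual, big.mark = ","),
              format(x$otc_cost_annual, big.mark = ","),
              format(x$selfmed_cost_annual, big.mark = ",")))
  cat(sprintf("  productivity loss (half-year): self-care %s, intervention %s\n",
              format(x$productivity_loss_halfyear_selfcare, big.mark = ","),
              format(x$productivity_loss_halfyear_intervention, big.mark = ",")))
  invisible(x)
}

#' The full base case
#'
#' Returns the base-case model and cost parameters together with the
#' uncertainty-distribution specifications used by the probabilistic
#' sensitivity analysis, and the set of calibratable parameter names.
#'
#' @return A list with elements `model` ([model_parameters()]), `cost`
#'   ([cost_parameters()]), `distributions` (named list of
#'   [distribution_spec()]) and `calibratable` (character vector).
#' @examples
#' bc <- base_case_parameters()
#' bc$model$p_progress_dys_to_endo12  # 0.184
#' @export
base_case_parameters <- function() {
  list(model = model_parameters(),
       cost = cost_parameters(),
       distributions = base_case_distributions(),
       calibratable = c("cure_dys", "cure_endo12", "cure_endo34",
                        "p_progress_endo12_to_34"))
}
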