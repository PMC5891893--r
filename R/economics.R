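#' Discount factor for a yearly cycle
#'
#' `(1 + rate)^(-cycle)`; cycle 0 (the first model year) is undiscounted.
#'
#' @param rate Annual discount rate (`>= 0`).
#' @param cycle Integer cycle index (`>= 0`). Vectorised.
#' @return Factor in `(0, 1]`.
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) stop("discount_factor(): rate must be non-negative", call. = FALSE)
  if (any(cycle < 0)) stop("discount_factor(): cycle must be non-negative", call. = FALSE)
  (1 + rate)^(-cycle)
}

#' Accumulate discounted costs over a cohort trace
#'
#' Costs are accrued on start-of-cycle occupancy and the recorded
#' within-cycle event intensities, then discounted by cycle index.
#'
#' Payer perspective (national health insurance): outpatient visits
#' (care-engaged dysmenorrhea/endometriosis mass, plus intervention-arm
#' maintenance follow-up, times the annual visit frequency and the
#' state-specific drug-inclusive visit cost), surgery (event mass times the
#' complexity-weighted operation fee) and the surgical-admission inpatient
#' cost attached to each surgery event.
#'
#' Societal perspective adds non-medical direct costs (OTC/self-medication,
#' self-care arm symptomatic person-years, split by the OTC-use proportion)
#' and opportunity costs: twice the half-year productivity loss per
#' symptomatic self-care person-year, or per managed (symptomatic +
#' maintenance) person-year in the intervention arm.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param cp [cost_parameters()].
#' @param perspective `"payer"` or `"societal"`.
#' @param rate Annual discount rate.
#' @param mp Optional [model_parameters()] supplying the OTC-use proportion
#'   (defaults to the base case value when omitted).
#' @return Discounted cost in JPY per cohort member (scalar), with a
#'   `"components"` attribute decomposing it into `direct_medical`,
#'   `direct_nonmedical` and `opportunity`.
#' @export
accumulate_costs <- function(trace, cp, perspective = c("payer", "societal"),
                             rate = 0.03, mp = NULL) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(trace, "cohort_trace"), inherits(cp, "cost_parameters"))
  ev <- trace$events
  h <- trace$horizon
  disc <- discount_factor(rate, ev$cycle)
  otc_share <- if (!is.null(mp)) mp$prop_otc_selfcare else 0.871

  visit_cost <- cp$visits_per_year *
    (ev$consult_dys * cp$visit_cost_dys +
       ev$consult_endo * cp$visit_cost_endo +
       ev$consult_maintenance * cp$visit_cost_dys)
  surgery_fee <- cp$prop_complex * cp$surgery_cost_complex +
    (1 - cp$prop_complex) * cp$surgery_cost_mild
  surgery_cost <- ev$surgery * (surgery_fee + cp$inpatient_cost_annual)
  direct_medical <- sum((visit_cost + surgery_cost) * disc)

  direct_nonmedical <- 0
  opportunity <- 0
  if (perspective == "societal") {
    symptomatic <- rowSums(trace$occupancy[1:h, c("dys", "endo12", "endo34"),
                                           drop = FALSE])
    if (trace$strategy == "self_care") {
      selfmed_unit <- otc_share * cp$otc_cost_annual +
        (1 - otc_share) * cp$selfmed_cost_annual
      direct_nonmedical <- sum(symptomatic * selfmed_unit * disc)
      opportunity <- sum(symptomatic * 2 * cp$productivity_loss_halfyear_selfcare * disc)
    } else {
      managed <- symptomatic + ev$consult_maintenance
      opportunity <- sum(managed * 2 * cp$productivity_loss_halfyear_intervention * disc)
    }
  }
  total <- direct_medical + direct_nonmedical + opportunity
  attr(total, "components") <- c(direct_medical = direct_medical,
                                 direct_nonmedical = direct_nonmedical,
                                 opportunity = opportunity)
  total
}

#' Accumulate discounted QALYs over a cohort trace
#'
#' Sum over cycles of start-of-cycle occupancy times the state utility
#' weight, discounted by cycle index. `well` and `cured` carry utility 1,
#' `dead` carries 0.
#'
#' @param trace A `cohort_trace`.
#' @param mp [model_parameters()] (utility weights, discount default).
#' @param rate Annual discount rate; defaults to `mp$discount_rate`.
#' @return Discounted QALYs per cohort member.
#' @export
accumulate_qalys <- function(trace, mp, rate = mp$discount_rate) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- trace$horizon
  u <- c(well = mp$u_well, dys = mp$u_dys, endo12 = mp$u_endo12,
         endo34 = mp$u_endo34, cured = mp$u_cured, dead = 0)
  occ <- trace$occupancy[1:h, , drop = FALSE]
  disc <- discount_factor(rate, 0:(h - 1))
  sum((occ %*% u[colnames(occ)]) * disc)
}

#' Evaluate one strategy end-to-end
#'
#' Runs the cohort and accumulates discounted and undiscounted costs (both
#' perspectives) and QALYs.
#'
#' @param mp,cp Model and cost parameters.
#' @param strategy Strategy name.
#' @return An `econ_result` list: `strategy`, `cost_payer`, `cost_societal`,
#'   `qalys`, undiscounted variants, `components` (societal decomposition)
#'   and the underlying `trace`.
#' @export
evaluate_strategy <- function(mp, cp, strategy = strategies()) {
  strategy <- match.arg(strategy)
  trace <- run_cohort(mp, strategy)
  r <- mp$discount_rate
  cost_soc <- accumulate_costs(trace, cp, "societal", rate = r, mp = mp)
  out <- list(
    strategy = strategy,
    cost_payer = as.numeric(accumulate_costs(trace, cp, "payer", rate = r, mp = mp)),
    cost_societal = as.numeric(cost_soc),
    qalys = accumulate_qalys(trace, mp, rate = r),
    cost_payer_undisc = as.numeric(accumulate_costs(trace, cp, "payer", rate = 0, mp = mp)),
    cost_societal_undisc = as.numeric(accumulate_costs(trace, cp, "societal",
                                                       rate = 0, mp = mp)),
    qalys_undisc = accumulate_qalys(trace, mp, rate = 0),
    components = attr(cost_soc, "components"),
    trace = trace)
  class(out) <- "econ_result"
  out
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result: %s>\n", x$strategy))
  cat(sprintf("  discounted cost: payer %s JPY, societal %s JPY\n",
              format(round(x$cost_payer), big.mark = ","),
              format(round(x$cost_societal), big.mark = ",")))
  cat(sprintf("  discounted QALYs: %.3f (undiscounted %.3f)\n",
              x$qalys, x$qalys_undisc))
  invisible(x)
}

#' Incremental cost-effectiveness and societal monetary value
#'
#' Compares the intervention against the comparator: incremental payer cost
#' and QALYs, their ratio (ICER, undefined when the incremental effect is
#' zero), the cost-effectiveness verdict against a willingness-to-pay
#' threshold, and the societal monetary value
#' `SMV = opportunity cost saved - incremental full direct cost consumed`
#' (equivalently the comparator's societal total minus the intervention's;
#' positive favours the intervention).
#'
#' @param a `econ_result` for the intervention.
#' @param b `econ_result` for the comparator (self-care).
#' @param wtp Willingness-to-pay threshold, JPY per QALY.
#' @return A `ce_result` list: `inc_cost`, `inc_effect`, `icer` (`NA` when
#'   undefined), `cost_effective`, `smv`, `smv_opportunity_saved`,
#'   `smv_direct_consumed`, `wtp`, plus the per-arm summaries.
#' @export
compare_strategies <- function(a, b, wtp = 5e6) {
  stopifnot(inherits(a, "econ_result"), inherits(b, "econ_result"))
  inc_cost <- a$cost_payer - b$cost_payer
  inc_effect <- a$qalys - b$qalys
  icer <- if (inc_effect == 0) NA_real_ else inc_cost / inc_effect
  opp_saved <- unname(b$components["opportunity"] - a$components["opportunity"])
  direct_consumed <- unname(
    (a$components["direct_medical"] + a$components["direct_nonmedical"]) -
      (b$components["direct_medical"] + b$components["direct_nonmedical"]))
  smv <- opp_saved - direct_consumed
  out <- list(inc_cost = inc_cost, inc_effect = inc_effect, icer = icer,
              cost_effective = !is.na(icer) && inc_effect > 0 && icer < wtp,
              smv = smv, smv_opportunity_saved = opp_saved,
              smv_direct_consumed = direct_consumed, wtp = wtp,
              intervention = a[c("strategy", "cost_payer", "cost_societal", "qalys")],
              comparator = b[c("strategy", "cost_payer", "cost_societal", "qalys")])
  class(out) <- "ce_result"
  out
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result: intervention vs self-care>\n")
  cat(sprintf("  incremental cost (payer): %s JPY; incremental effect: %.3f QALYs\n",
              format(round(x$inc_cost), big.mark = ","), x$inc_effect))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero incremental effect)\n")
  } else {
    cat(sprintf("  ICER: %s JPY/QALY (%scost-effective at WTP %s)\n",
                format(round(x$icer), big.mark = ","),
                if (x$cost_effective) "" else "not ",
                format(x$wtp, big.mark = ",", scientific = FALSE)))
  }
  cat(sprintf("  SMV: %s JPY (positive favours the intervention)\n",
              format(round(x$smv), big.mark = ",")))
  invisible(x)
}
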