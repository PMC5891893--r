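#' Health states of the cohort model
#'
#' Five modelled health states plus an entry pool: `well` (susceptible, no
#' menstrual disorder yet), `dys` (dysmenorrhea), `endo12` (stage I/II
#' endometriosis), `endo34` (stage III/IV endometriosis), `cured`
#' (remission) and the absorbing `dead` (other-cause death). The entry pool
#' is needed because dysmenorrhea arises from an age-dependent incidence;
#' `well` members carry utility 1 and no cost.
#'
#' @return Character vector of state names, in matrix order.
#' @export
health_states <- function() c("well", "dys", "endo12", "endo34", "cured", "dead")

#' Comparator strategies
#' @return Character vector `c("self_care", "intervention")`.
#' @export
strategies <- function() c("self_care", "intervention")

# Care-engagement fraction by age: the intervention arm is under guideline
# care with certainty; the self-care arm contacts the medical system only at
# its age-dependent care-seeking proportion.
.engagement <- function(mp, strategy, ages) {
  if (strategy == "intervention") {
    list(dys = rep(1, length(ages)), endo = rep(1, length(ages)))
  } else {
    list(dys = schedule_value(mp$visit_prop_dys, ages),
         endo = schedule_value(mp$visit_prop_endo, ages))
  }
}

# Strategy-effective annual transition inputs at given ages.
.effective_rates <- function(mp, strategy, ages) {
  eng <- .engagement(mp, strategy, ages)
  p12 <- mp$p_progress_dys_to_endo12
  p34 <- mp$p_progress_endo12_to_34
  if (strategy == "intervention") {
    p12 <- apply_odds_ratio(p12, mp$or_develop_endo12)
    p34 <- apply_odds_ratio(p34, mp$or_progress_endo34)
  }
  surg <- mp$p_surgery_endo * eng$endo
  list(
    incidence = schedule_value(mp$incidence_dysmenorrhea, ages),
    q = mortality_at(mp$life_table, ages),
    p12 = rep(p12, length(ages)),
    p34 = rep(p34, length(ages)),
    cure_dys = mp$cure_dys * eng$dys,
    cure_e12 = mp$cure_endo12 * eng$endo,
    cure_e34 = mp$cure_endo34 * eng$endo,
    surgery = surg,
    recurrence = rep(mp$p_recurrence, length(ages)),
    eng = eng)
}

#' Yearly transition probability matrix at one age
#'
#' Assembles the 6-state transition matrix for a strategy at a given age.
#' Within a cycle the clinical branches apply in tree order: other-cause
#' death first; then disease progression among survivors; then cure (and
#' surgery) among the non-progressors; the residual stays in state. The
#' conditional ordering keeps every row valid for any probabilities in
#' `[0, 1]` (so the full published one-way ranges are explorable); a branch
#' whose probabilities genuinely sum above one (e.g. cure + surgery > 1)
#' raises a model-construction error rather than being silently
#' renormalised.
#'
#' @param mp [model_parameters()].
#' @param strategy `"self_care"` or `"intervention"`.
#' @param age Age in years at the start of the cycle.
#' @return 6 x 6 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(mp, strategy = strategies(), age) {
  strategy <- match.arg(strategy)
  stopifnot(length(age) == 1L, age >= 0)
  er <- .effective_rates(mp, strategy, age)
  .matrix_from_rates(er, 1L, mp$surgery_to_cured)
}

#' Run the yearly Markov cohort
#'
#' Propagates a closed cohort that starts entirely in `well` at
#' `mp$start_age` through `mp$horizon` yearly cycles, recording state
#' occupancy at every cycle boundary and the within-cycle event intensities
#' (care-engaged person-mass for consultations, surgery mass, recurrence and
#' endometriosis entry flows) needed for costing and prevalence work.
#'
#' @param mp [model_parameters()].
#' @param strategy `"self_care"` or `"intervention"`.
#' @param init Optional initial occupancy vector over [health_states()]
#'   (defaults to all mass in `well`). Must sum to 1.
#' @return A `cohort_trace`: list with `occupancy`
#'   (`(horizon + 1) x 6` matrix, rows = cycle boundaries), `events`
#'   (data.frame, one row per cycle), `ages`, `strategy`, `horizon`.
#' @export
run_cohort <- function(mp, strategy = strategies(), init = NULL) {
  strategy <- match.arg(strategy)
  h <- as.integer(mp$horizon)
  st <- health_states()
  ages <- mp$start_age + 0:(h - 1)
  er <- .effective_rates(mp, strategy, ages)

  occ <- matrix(0, h + 1, 6, dimnames = list(cycle = 0:h, state = st))
  if (is.null(init)) init <- c(1, 0, 0, 0, 0, 0)
  stopifnot(length(init) == 6L, abs(sum(init) - 1) < 1e-9, all(init >= 0))
  occ[1, ] <- init

  for (k in seq_len(h)) {
    M <- .matrix_from_rates(er, k, mp$surgery_to_cured)
    occ[k + 1, ] <- occ[k, ] %*% M
  }

  pre <- occ[1:h, , drop = FALSE]  # start-of-cycle occupancy
  surv <- 1 - er$q
  maintenance <- if (strategy == "intervention" && mp$maintenance_in_cured)
    pre[, "cured"] else rep(0, h)
  events <- data.frame(
    cycle = 0:(h - 1),
    age = ages,
    consult_dys = pre[, "dys"] * er$eng$dys,
    consult_endo = (pre[, "endo12"] + pre[, "endo34"]) * er$eng$endo,
    consult_maintenance = maintenance,
    surgery = (pre[, "endo12"] * (1 - er$p34) + pre[, "endo34"]) * surv * er$surgery,
    recurrence = pre[, "cured"] * surv * er$recurrence,
    entries_dys = pre[, "well"] * surv * er$incidence,
    entries_endo12 = pre[, "dys"] * surv * er$p12,
    entries_endo34 = pre[, "endo12"] * surv * er$p34,
    stay = {
      sc <- if (mp$surgery_to_cured) er$surgery else 0
      pre[, "dys"] * surv * (1 - er$p12) * (1 - er$cure_dys) +
        pre[, "endo12"] * surv * (1 - er$p34) * (1 - er$cure_e12 - sc) +
        pre[, "endo34"] * surv * (1 - er$cure_e34 - sc)
    })
  structure(list(occupancy = occ, events = events, ages = c(ages, mp$start_age + h),
                 strategy = strategy, horizon = h, start_age = mp$start_age),
            class = "cohort_trace")
}

# Matrix assembly from precomputed per-age effective rates (cycle index k).
# Branches apply in tree order: death, then progression among survivors,
# then cure/surgery among non-progressors; residual stays in state.
.matrix_from_rates <- function(er, k, surgery_to_cured) {
  st <- health_states()
  M <- matrix(0, 6, 6, dimnames = list(st, st))
  q <- er$q[k]
  surg_c <- if (surgery_to_cured) er$surgery[k] else 0
  check_branch <- function(state, ...) {
    p <- c(...)
    if (any(p < 0) || sum(p) > 1 + 1e-12) {
      stop(sprintf("transition branch out of `%s` sums to %.4f, outside [0, 1]",
                   state, sum(p)), call. = FALSE)
    }
    sum(p)
  }
  check_branch("well", er$incidence[k])
  check_branch("dys", er$p12[k]); check_branch("dys", er$cure_dys[k])
  check_branch("endo12", er$p34[k])
  exit12 <- check_branch("endo12", er$cure_e12[k], surg_c)
  exit34 <- check_branch("endo34", er$cure_e34[k], surg_c)
  check_branch("cured", er$recurrence[k])
  rows <- list(
    well = c(dys = er$incidence[k]),
    dys = c(endo12 = er$p12[k], cured = er$cure_dys[k] * (1 - er$p12[k])),
    endo12 = c(endo34 = er$p34[k], cured = exit12 * (1 - er$p34[k])),
    endo34 = c(cured = exit34),
    cured = c(dys = er$recurrence[k]))
  for (s in names(rows)) {
    out <- rows[[s]]
    M[s, names(out)] <- out * (1 - q)
    M[s, s] <- M[s, s] + (1 - sum(out)) * (1 - q)
    M[s, "dead"] <- q
  }
  M["dead", "dead"] <- 1
  M
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace: %s, %d yearly cycles, ages %d-%d>\n",
              x$strategy, x$horizon, x$start_age, x$start_age + x$horizon))
  cat("final occupancy:\n")
  print(round(x$occupancy[nrow(x$occupancy), ], 4))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  data.frame(cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
             age = rep(x$ages, times = ncol(occ)),
             state = rep(colnames(occ), each = nrow(occ)),
             occupancy = as.vector(occ), row.names = NULL)
}

#' Cumulative endometriosis burden of a cohort run
#'
#' Two measures of how much endometriosis the cohort accumulates over the
#' horizon, per cohort member:
#' \describe{
#'   \item{`incidence`}{cumulative new-entry mass into the endometriosis
#'     complex (flow from dysmenorrhea into stage I/II; re-entries after
#'     cure and relapse count again). Default.}
#'   \item{`prevalence`}{endometriosis person-years, i.e. the sum over
#'     cycles of stage I/II + III/IV occupancy — the "accompaniment"
#'     (disease burden) measure used when comparing strategies against the
#'     reported ~95% reduction.}
#' }
#'
#' @param trace A `cohort_trace`.
#' @param measure `"incidence"` or `"prevalence"`.
#' @return Non-negative scalar.
#' @export
cumulative_endometriosis <- function(trace, measure = c("incidence", "prevalence")) {
  measure <- match.arg(measure)
  stopifnot(inherits(trace, "cohort_trace"))
  if (measure == "incidence") {
    sum(trace$events$entries_endo12)
  } else {
    h <- trace$horizon
    sum(trace$occupancy[1:h, c("endo12", "endo34")])
  }
}

#' Scale per-capita prevalence to national case counts
#'
#' Multiplies the modelled per-capita endometriosis point prevalence at each
#' age by female population counts, returning per-age-group case counts and
#' the cumulative national count across the modelled ages.
#'
#' @param trace A `cohort_trace` (self-care arm for external calibration).
#' @param pop A `population_table` covering every modelled age.
#' @return List with `by_age` (data.frame: age, prevalence, cases),
#'   `by_group` (data.frame: age_low, age_high, cases, prevalence) and
#'   `cumulative` (total cases).
#' @export
prevalence_counts <- function(trace, pop) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(pop, "population_table"))
  ages <- trace$ages
  prev <- rowSums(trace$occupancy[, c("endo12", "endo34"), drop = FALSE])
  counts <- prev * population_at(pop, ages)   # errors on missing age group
  by_age <- data.frame(age = ages, prevalence = prev, cases = counts)
  grp <- vapply(seq_len(nrow(pop)), function(i) {
    sel <- ages >= pop$age_low[i] & ages <= pop$age_high[i]
    sum(counts[sel])
  }, numeric(1))
  gsel <- grp > 0 | (pop$age_low <= max(ages) & pop$age_high >= min(ages))
  by_group <- data.frame(age_low = pop$age_low[gsel], age_high = pop$age_high[gsel],
                         cases = grp[gsel])
  by_group$prevalence <- vapply(seq_len(nrow(by_group)), function(i) {
    sel <- ages >= by_group$age_low[i] & ages <= by_group$age_high[i]
    if (!any(sel)) return(NA_real_)
    mean(prev[sel])
  }, numeric(1))
  list(by_age = by_age, by_group = by_group, cumulative = sum(counts))
}

#' Individual-level cross-check simulator
#'
#' Monte Carlo microsimulation of `n` independent individuals through the
#' same transition structure, used in the test suite as an independent
#' oracle for the cohort (expected-value) engine: cohort occupancy must fall
#' within Monte-Carlo error of the microsimulated fractions.
#'
#' @param mp [model_parameters()].
#' @param strategy Strategy name.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Occupancy-fraction matrix of the same shape as
#'   `run_cohort()$occupancy`.
#' @export
simulate_cohort_micro <- function(mp, strategy = strategies(), n = 1e5, seed = 1L) {
  strategy <- match.arg(strategy)
  h <- as.integer(mp$horizon)
  ages <- mp$start_age + 0:(h - 1)
  er <- .effective_rates(mp, strategy, ages)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  state <- rep(1L, n)  # everyone starts in `well`
  occ <- matrix(0, h + 1, 6, dimnames = list(cycle = 0:h, state = health_states()))
  occ[1, ] <- tabulate(state, 6) / n
  for (k in seq_len(h)) {
    M <- .matrix_from_rates(er, k, mp$surgery_to_cured)
    cum <- t(apply(M, 1, cumsum))
    u <- stats::runif(n)
    new_state <- integer(n)
    for (s in 1:6) {
      idx <- state == s
      if (any(idx)) new_state[idx] <- pmin(findInterval(u[idx], cum[s, ]) + 1L, 6L)
    }
    state <- new_state
    occ[k + 1, ] <- tabulate(state, 6) / n
  }
  occ
}
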