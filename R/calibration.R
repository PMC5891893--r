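#' Calibration targets
#'
#' A target set is a data.frame with columns `name`, `kind`
#' (`"cumulative_count"` or `"age_specific_prevalence"`), `age_low`,
#' `age_high` (ignored for cumulative counts), `observed` and a
#' non-negative `weight`. The shipped default emulates the external
#' evidence the model is calibrated against: a national cumulative
#' endometriosis case count of about 210,000 across the modelled ages, and
#' an age-specific prevalence profile rising from adolescence to a peak
#' around age 30. Age groups of 35 and over get weight 0: the model is
#' known to over-predict there (recurrence after remission is assumed
#' life-long) and that discrepancy is reproduced, not fixed.
#'
#' @return Data frame of targets.
#' @export
default_calibration_targets <- function() {
  data.frame(
    name = c("cumulative_endometriosis_cases", "prev_15_19", "prev_20_24",
             "prev_25_29", "prev_30_34", "prev_35_39"),
    kind = c("cumulative_count", rep("age_specific_prevalence", 5)),
    age_low = c(NA, 15, 20, 25, 30, 35),
    age_high = c(NA, 19, 24, 29, 34, 39),
    observed = c(210000, 0.003, 0.010, 0.020, 0.028, 0.028),
    weight = c(1, 1, 1, 1, 1, 0))
}

#' Read calibration targets from CSV
#'
#' Schema as in [default_calibration_targets()].
#' @param path CSV path.
#' @return Validated targets data.frame.
#' @export
read_calibration_targets <- function(path) {
  df <- utils::read.csv(path)
  validate_targets(df)
  df
}

validate_targets <- function(targets) {
  req <- c("name", "kind", "observed", "weight")
  if (!is.data.frame(targets) || !all(req %in% names(targets)) || nrow(targets) == 0) {
    stop("calibration targets must be a non-empty data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(targets$kind %in% c("cumulative_count", "age_specific_prevalence"))) {
    stop("unknown target kind; use cumulative_count or age_specific_prevalence",
         call. = FALSE)
  }
  if (any(targets$weight < 0)) stop("target weights must be non-negative", call. = FALSE)
  if (all(targets$weight == 0)) {
    stop("all target weights are zero: no information to calibrate against",
         call. = FALSE)
  }
  invisible(targets)
}

# Substitute named free parameters into a model_parameters object.
.substitute_params <- function(mp, values) {
  for (nm in names(values)) {
    if (!nm %in% names(mp)) stop(sprintf("unknown free parameter `%s`", nm),
                                 call. = FALSE)
    mp[[nm]] <- unname(values[nm])
  }
  validate_parameters(mp)
  mp
}

# Per-target model predictions for a self-care trace.
.target_predictions <- function(trace, targets, pop) {
  pc <- prevalence_counts(trace, pop)
  vapply(seq_len(nrow(targets)), function(i) {
    if (targets$kind[i] == "cumulative_count") {
      pc$cumulative
    } else {
      sel <- pc$by_age$age >= targets$age_low[i] & pc$by_age$age <= targets$age_high[i]
      if (!any(sel)) return(NA_real_)
      mean(pc$by_age$prevalence[sel])
    }
  }, numeric(1))
}

#' Calibration objective: weighted squared relative residuals
#'
#' Substitutes the free parameters into the model, runs the self-care
#' cohort (calibration mirrors the natural-history arm), and returns the
#' weighted sum of squared relative residuals against the targets. Targets
#' whose age range falls outside the modelled ages contribute nothing.
#'
#' @param values Named numeric vector of free parameter values (names must
#'   be [model_parameters()] fields).
#' @param targets Targets data.frame (see [default_calibration_targets()]).
#' @param mp,cp Model and cost parameters (costs are carried for interface
#'   symmetry; the objective is purely epidemiological).
#' @param pop A `population_table`.
#' @return Non-negative scalar.
#' @export
calibration_objective <- function(values, targets, mp, cp = NULL, pop = make_population()) {
  validate_targets(targets)
  mp2 <- .substitute_params(mp, values)
  trace <- run_cohort(mp2, "self_care")
  pred <- .target_predictions(trace, targets, pop)
  rel <- (pred - targets$observed) / targets$observed
  keep <- !is.na(rel)
  sum(targets$weight[keep] * rel[keep]^2)
}

#' Calibrate unobserved model parameters against prevalence targets
#'
#' Derivative-free, reproducible point calibration: a coarse bounded grid
#' search (full factorial at `grid_step` resolution for up to two free
#' parameters, a reduced 7-point-per-dimension lattice above that) followed
#' by Nelder-Mead refinement with out-of-bounds penalty. Reports
#' non-convergence honestly via the `converged` flag.
#'
#' @param targets Targets data.frame.
#' @param free Character vector of free parameter names; defaults to the
#'   unprinted stage I/II to III/IV progression probability.
#' @param bounds Named list (or 2-column matrix) of `c(lower, upper)` per
#'   free parameter. Default `[0.01, 0.5]` for the progression probability
#'   and `[0, 1]` for cure probabilities.
#' @param mp,cp,pop Model, cost and population inputs.
#' @param grid_step Grid resolution for the coarse stage.
#' @return A `calibration_result`: `par` (named fitted values), `objective`,
#'   `residuals` (per-target data.frame), `converged`, `model` (the
#'   calibrated [model_parameters()]).
#' @export
calibrate_model <- function(targets = default_calibration_targets(),
                            free = "p_progress_endo12_to_34",
                            bounds = NULL,
                            mp = model_parameters(), cp = NULL,
                            pop = make_population(),
                            grid_step = 0.02) {
  validate_targets(targets)
  stopifnot(length(free) >= 1)
  # endometriosis cure bounds keep cure + surgery <= 1 within one branch
  default_bounds <- list(p_progress_endo12_to_34 = c(0.01, 0.5),
                         cure_dys = c(0.05, 1), cure_endo12 = c(0.05, 0.93),
                         cure_endo34 = c(0.05, 0.93))
  if (is.null(bounds)) {
    bounds <- lapply(free, function(f) default_bounds[[f]] %||% c(0, 1))
    names(bounds) <- free
  }
  bl <- vapply(free, function(f) bounds[[f]][1], numeric(1))
  bu <- vapply(free, function(f) bounds[[f]][2], numeric(1))
  if (any(bl >= bu)) stop("calibrate_model(): infeasible bounds", call. = FALSE)

  obj <- function(x) {
    names(x) <- free
    if (any(x < bl) || any(x > bu)) {
      # quadratic out-of-bounds penalty keeps Nelder-Mead inside the box
      xc <- pmin(pmax(x, bl), bu)
      base <- calibration_objective(xc, targets, mp, cp, pop)
      return(base + 1e3 * sum(((x - xc) / (bu - bl))^2) + 1)
    }
    calibration_objective(x, targets, mp, cp, pop)
  }

  # Stage 1: bounded grid.
  k <- length(free)
  grids <- lapply(seq_len(k), function(i) {
    if (k <= 2) seq(bl[i], bu[i], by = grid_step)
    else seq(bl[i], bu[i], length.out = 7)
  })
  grid <- as.matrix(expand.grid(grids))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]

  # Stage 2: Nelder-Mead refinement (optimize() for a single parameter).
  if (k == 1) {
    lo <- max(bl, best - 2 * grid_step); hi <- min(bu, best + 2 * grid_step)
    o <- stats::optimize(function(x) obj(x), interval = c(lo, hi), tol = 1e-6)
    par <- o$minimum; value <- o$objective; conv <- TRUE
  } else {
    o <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
    par <- pmin(pmax(o$par, bl), bu)
    value <- obj(par)
    conv <- o$convergence == 0
  }
  names(par) <- free
  # boundary solutions are reported but flagged as non-interior
  at_boundary <- any(abs(par - bl) < 1e-4 * (bu - bl) | abs(par - bu) < 1e-4 * (bu - bl))

  mp_fit <- .substitute_params(mp, par)
  trace <- run_cohort(mp_fit, "self_care")
  pred <- .target_predictions(trace, targets, pop)
  res <- data.frame(targets[, c("name", "kind", "observed", "weight")],
                    predicted = pred,
                    rel_residual = (pred - targets$observed) / targets$observed)
  out <- list(par = par, objective = value,
              residuals = res, converged = conv && is.finite(value),
              at_boundary = at_boundary, model = mp_fit)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  fitted parameters:\n")
  for (nm in names(x$par)) cat(sprintf("    %s = %.4f\n", nm, x$par[nm]))
  cat(sprintf("  objective: %.6g | converged: %s%s\n", x$objective, x$converged,
              if (x$at_boundary) " (boundary solution)" else ""))
  print(x$residuals, row.names = FALSE, digits = 4)
  invisible(x)
}
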