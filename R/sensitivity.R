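#' Set a single named parameter in a parameter set
#'
#' Helper used by the deterministic sensitivity analysis and the PSA: `name`
#' may be any scalar field of [model_parameters()] or [cost_parameters()].
#' For the age-schedule fields (`incidence_dysmenorrhea`, `visit_prop_dys`,
#' `visit_prop_endo`) the schedule is replaced by a constant at `value`,
#' which is how a printed scalar range for an age-dependent quantity is
#' explored.
#'
#' @param params List with `model` and `cost` components.
#' @param name Parameter name.
#' @param value New value.
#' @return Modified `params`.
#' @export
set_parameter <- function(params, name, value) {
  mp <- params$model; cp <- params$cost
  sched_fields <- c("incidence_dysmenorrhea", "visit_prop_dys", "visit_prop_endo")
  if (name %in% sched_fields) {
    mp[[name]] <- constant_schedule(value)
  } else if (name %in% names(mp) && is.numeric(mp[[name]])) {
    mp[[name]] <- value
  } else if (name %in% names(cp)) {
    cp[[name]] <- value
  } else {
    valid <- c(setdiff(names(mp), "life_table"), names(cp))
    stop(sprintf("unknown parameter `%s`; valid names: %s", name,
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  validate_parameters(mp); validate_parameters(cp)
  params$model <- mp; params$cost <- cp
  params
}

# Full pipeline evaluation of a parameter set -> one scalar outcome.
.pipeline_outcome <- function(params, outcome = c("icer", "inc_cost", "smv")) {
  outcome <- match.arg(outcome)
  a <- evaluate_strategy(params$model, params$cost, "intervention")
  b <- evaluate_strategy(params$model, params$cost, "self_care")
  ce <- compare_strategies(a, b)
  switch(outcome,
         icer = ce$icer,
         inc_cost = a$cost_societal - b$cost_societal,
         smv = ce$smv)
}

#' One-way deterministic sensitivity of a pipeline outcome
#'
#' Re-runs the full two-arm pipeline at each endpoint of a parameter range,
#' holding everything else at base case.
#'
#' @param params List with `model` and `cost` (e.g. [base_case_parameters()]).
#' @param name Parameter name (see [set_parameter()]).
#' @param low,high Range endpoints, `low < high`.
#' @param outcome `"icer"` (payer ICER), `"inc_cost"` (societal incremental
#'   cost) or `"smv"`.
#' @return One-row data.frame: `parameter`, `low`, `high`, `outcome_low`,
#'   `outcome_high`, `outcome_base`, `spread`, `non_monotone` (`TRUE` when
#'   the base outcome falls outside the endpoint interval).
#' @export
one_way <- function(params, name, low, high, outcome = c("icer", "inc_cost", "smv")) {
  outcome <- match.arg(outcome)
  if (!(low < high)) stop("one_way(): need low < high", call. = FALSE)
  o_base <- .pipeline_outcome(params, outcome)
  o_low <- .pipeline_outcome(set_parameter(params, name, low), outcome)
  o_high <- .pipeline_outcome(set_parameter(params, name, high), outcome)
  data.frame(parameter = name, low = low, high = high,
             outcome_low = o_low, outcome_high = o_high, outcome_base = o_base,
             spread = abs(o_high - o_low),
             non_monotone = o_base < min(o_low, o_high) - 1e-9 |
               o_base > max(o_low, o_high) + 1e-9)
}

#' Default one-way ranges
#'
#' The published ranges explored in the deterministic sensitivity analysis:
#' ten parameters for the payer-perspective ICER and seven for the
#' societal-perspective incremental cost.
#'
#' @param perspective `"payer"` or `"societal"`.
#' @return Data frame with columns `parameter`, `low`, `high`.
#' @export
default_tornado_ranges <- function(perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (perspective == "payer") {
    data.frame(
      parameter = c("cure_dys", "or_develop_endo12", "u_endo34",
                    "visit_prop_endo", "p_progress_dys_to_endo12",
                    "discount_rate", "u_dys", "p_recurrence", "cure_endo12",
                    "u_endo12"),
      low = c(0.643, 0.2, 0.15, 0.0, 0.179, 0.01, 0.63, 0.206, 0.322, 0.63),
      high = c(0.957, 0.7, 0.557, 0.07, 0.189, 0.05, 0.644, 0.239, 0.478, 0.644))
  } else {
    data.frame(
      parameter = c("discount_rate", "p_recurrence", "cure_endo12",
                    "or_develop_endo12", "p_progress_dys_to_endo12",
                    "cure_dys", "visit_prop_endo"),
      low = c(0.01, 0.206, 0.322, 0.2, 0.179, 0.643, 0.0),
      high = c(0.05, 0.239, 0.478, 0.7, 0.189, 0.957, 0.07))
  }
}

#' Tornado analysis
#'
#' Runs [one_way()] for every supplied range and sorts the entries by
#' spread, descending. Deterministic; the ordering does not depend on the
#' order the ranges are supplied in.
#'
#' @param params Parameter set (`model` + `cost`).
#' @param ranges Data frame with `parameter`, `low`, `high`; defaults to the
#'   published payer-perspective set.
#' @param outcome Outcome passed to [one_way()].
#' @return Data frame of tornado entries sorted by spread (class
#'   `tornado_result`).
#' @export
tornado <- function(params, ranges = default_tornado_ranges("payer"),
                    outcome = c("icer", "inc_cost", "smv")) {
  outcome <- match.arg(outcome)
  if (nrow(ranges) == 0) {
    out <- data.frame(parameter = character(), low = numeric(), high = numeric(),
                      outcome_low = numeric(), outcome_high = numeric(),
                      outcome_base = numeric(), spread = numeric(),
                      non_monotone = logical())
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i) {
      if (ranges$low[i] == ranges$high[i]) {
        o <- .pipeline_outcome(params, outcome)
        data.frame(parameter = ranges$parameter[i], low = ranges$low[i],
                   high = ranges$high[i], outcome_low = o, outcome_high = o,
                   outcome_base = o, spread = 0, non_monotone = FALSE)
      } else {
        one_way(params, ranges$parameter[i], ranges$low[i], ranges$high[i], outcome)
      }
    }))
    out <- out[order(-out$spread, out$parameter), ]
    rownames(out) <- NULL
  }
  attr(out, "outcome") <- outcome
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Draw one joint parameter sample for the PSA
#'
#' Independently samples every parameter that has a non-fixed
#' [distribution_spec()], respecting each family and domain truncation, and
#' returns the modified parameter set. Uses the current RNG stream; callers
#' wanting reproducibility seed before calling (as [run_psa()] does,
#' per-draw).
#'
#' @param params Parameter set (`model` + `cost`).
#' @param dists Named list of `distribution_spec`s (defaults to the set in
#'   `params$distributions`, else [base_case_distributions()]).
#' @return List with `params` (modified set) and `values` (named numeric
#'   vector of the sampled values).
#' @export
sample_parameters <- function(params, dists = NULL) {
  dists <- dists %||% params$distributions %||% base_case_distributions()
  values <- numeric(0)
  for (nm in names(dists)) {
    v <- sample_spec(dists[[nm]], 1)
    params <- set_parameter(params, nm, v)
    values[nm] <- v
  }
  list(params = params, values = values)
}

#' Probabilistic sensitivity analysis
#'
#' `n` Monte-Carlo evaluations of the full two-arm pipeline, each with an
#' independent joint parameter draw. Each draw `i` uses its own RNG stream
#' seeded deterministically from `seed + i`, so results are bit-identical
#' across reruns and independent of `n` (draw 17 is the same whether you
#' ask for 100 or 10,000 draws).
#'
#' @param params Parameter set (`model` + `cost`, typically calibrated).
#' @param dists Distribution set (see [sample_parameters()]).
#' @param n Number of iterations (`>= 1`).
#' @param seed Base integer seed (default 20180410).
#' @param keep_params Keep the sampled parameter values per draw
#'   (default `TRUE`).
#' @return A `psa_result`: `draws` (data.frame with `iteration`, `inc_cost`
#'   (payer), `inc_effect`, `inc_cost_societal`, and the sampled parameter
#'   columns), `n`, `seed`.
#' @export
run_psa <- function(params, dists = NULL, n = 10000, seed = 20180410,
                    keep_params = TRUE) {
  stopifnot(n >= 1)
  dists <- dists %||% params$distributions %||% base_case_distributions()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # one stream per draw index; base seeds are spaced so that different
    # seeds do not share streams for any n up to 1,000,003
    set.seed(as.integer((as.double(seed) * 1000003 + i) %% 2147483647))
    s <- sample_parameters(params, dists)
    a <- evaluate_strategy(s$params$model, s$params$cost, "intervention")
    b <- evaluate_strategy(s$params$model, s$params$cost, "self_care")
    row <- c(iteration = i,
             inc_cost = a$cost_payer - b$cost_payer,
             inc_effect = a$qalys - b$qalys,
             inc_cost_societal = a$cost_societal - b$cost_societal)
    if (keep_params) row <- c(row, s$values)
    rows[[i]] <- row
  }
  draws <- as.data.frame(do.call(rbind, rows))
  structure(list(draws = draws, n = n, seed = seed), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d draws, seed %d>\n", x$n, x$seed))
  s <- psa_summary(x)
  cat(sprintf("  incremental cost (payer): mean %s JPY (95%% %s, %s)\n",
              format(round(s$inc_cost["mean"]), big.mark = ","),
              format(round(s$inc_cost["p2.5"]), big.mark = ","),
              format(round(s$inc_cost["p97.5"]), big.mark = ",")))
  cat(sprintf("  incremental effect: mean %.3f QALYs (95%% %.3f, %.3f)\n",
              s$inc_effect["mean"], s$inc_effect["p2.5"], s$inc_effect["p97.5"]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit
#' (`wtp * inc_effect - inc_cost > 0`) at each willingness-to-pay value.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid WTP values, JPY per QALY; defaults to 0 to 5 million in
#'   50,000-JPY steps.
#' @return A `ceac_curve` data.frame: `wtp`, `acceptance`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 5e6, by = 5e4)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) >= 1)
  acc <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$inc_effect - psa$draws$inc_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, acceptance = acc),
            class = c("ceac_curve", "data.frame"))
}

#' Summarise a PSA
#'
#' Means, empirical 2.5/97.5 percentiles, normal-theory 95% intervals
#' (mean +/- 1.96 sd, mirroring summaries that assume normal cost and
#' effect distributions) and a normal-approximation p-value against zero
#' for incremental cost and effect.
#'
#' @param psa A `psa_result` with at least 2 draws.
#' @return List with named vectors `inc_cost` and `inc_effect`
#'   (`mean`, `sd`, `p2.5`, `p97.5`, `normal_low`, `normal_high`,
#'   `p_value`).
#' @export
psa_summary <- function(psa) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) >= 2)
  summ <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    q <- unname(stats::quantile(x, c(0.025, 0.975)))
    z <- if (s > 0) abs(m) / (s / sqrt(length(x))) else Inf
    c(mean = m, sd = s, p2.5 = q[1], p97.5 = q[2],
      normal_low = m - stats::qnorm(0.975) * s,
      normal_high = m + stats::qnorm(0.975) * s,
      p_value = 2 * stats::pnorm(-z))
  }
  list(inc_cost = summ(psa$draws$inc_cost),
       inc_effect = summ(psa$draws$inc_effect))
}

#' Plot a cost-effectiveness acceptability curve
#' @param x A `ceac_curve`.
#' @param wtp_mark Optional WTP threshold(s) to mark (JPY/QALY).
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, wtp_mark = c(1e5, 5e6)) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$wtp, y = .data$acceptance)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = wtp_mark, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.1fM", v / 1e6)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (JPY per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#' @param x A `tornado_result`.
#' @return A ggplot object.
#' @export
plot_tornado <- function(x) {
  d <- as.data.frame(x)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  d$lo <- pmin(d$outcome_low, d$outcome_high)
  d$hi <- pmax(d$outcome_low, d$outcome_high)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$outcome_base),
                        linetype = "dashed") +
    ggplot2::labs(x = attr(x, "outcome") %||% "outcome", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
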