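#' Run the calibrated base-case analysis end-to-end
#'
#' Convenience wrapper for the whole pipeline: (optionally) calibrate the
#' unobserved progression parameter against the prevalence targets, run
#' both strategy arms, and compute the incremental comparison and the
#' endometriosis-burden reduction.
#'
#' @param params Parameter set (`model` + `cost` [+ `distributions`]);
#'   defaults to [base_case_parameters()].
#' @param calibrate Run [calibrate_model()] first (default `TRUE`).
#' @param targets,free Calibration targets and free parameter names.
#' @param pop Population table for prevalence scaling.
#' @param wtp Willingness-to-pay threshold (JPY/QALY).
#' @return A `base_case_result`: `ce` ([compare_strategies()] output),
#'   `arms` (list of `econ_result`), `calibration` (or `NULL`),
#'   `endo_reduction` (list with `incidence` and `prevalence` relative
#'   reductions, in percent), `params` (calibrated set), `prevalence`
#'   (self-care national counts).
#' @export
run_base_case <- function(params = base_case_parameters(), calibrate = TRUE,
                          targets = default_calibration_targets(),
                          free = "p_progress_endo12_to_34",
                          pop = make_population(), wtp = 5e6) {
  calib <- NULL
  if (isTRUE(calibrate)) {
    calib <- calibrate_model(targets = targets, free = free, mp = params$model,
                             cp = params$cost, pop = pop)
    params$model <- calib$model
  }
  a <- evaluate_strategy(params$model, params$cost, "intervention")
  b <- evaluate_strategy(params$model, params$cost, "self_care")
  ce <- compare_strategies(a, b, wtp = wtp)
  red <- function(measure) {
    sc <- cumulative_endometriosis(b$trace, measure)
    iv <- cumulative_endometriosis(a$trace, measure)
    if (sc == 0) return(NA_real_)
    100 * (1 - iv / sc)
  }
  out <- list(ce = ce, arms = list(intervention = a, self_care = b),
              calibration = calib,
              endo_reduction = list(incidence = red("incidence"),
                                    prevalence = red("prevalence")),
              prevalence = prevalence_counts(b$trace, pop),
              params = params)
  class(out) <- "base_case_result"
  out
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("== Base case ==\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("calibrated: %s\n",
                paste(sprintf("%s = %.4f", names(x$calibration$par),
                              x$calibration$par), collapse = ", ")))
  }
  for (arm in x$arms) print(arm)
  print(x$ce)
  cat(sprintf("endometriosis burden reduction: %.1f%% (person-years), %.1f%% (new entries)\n",
              x$endo_reduction$prevalence, x$endo_reduction$incidence))
  cat(sprintf("self-care national endometriosis cases (modelled ages): %s\n",
              format(round(x$prevalence$cumulative), big.mark = ",")))
  invisible(x)
}

#' Export a cohort trace as tidy CSV
#'
#' One row per cycle/state with occupancy, plus the event intensities.
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  ev_path <- sub("\\.csv$", "_events.csv", path)
  utils::write.csv(trace$events, ev_path, row.names = FALSE)
  invisible(path)
}

#' Write base-case report artifacts
#'
#' Emits a per-arm expected cost/effectiveness table (both perspectives),
#' the incremental row with the ICER and verdict, and the societal
#' monetary value block, as CSV and JSON, plus per-arm trace exports and a
#' run manifest.
#'
#' @param res A `base_case_result`.
#' @param dir Output directory.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the files written.
#' @export
write_base_case_report <- function(res, dir = ".", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ce <- res$ce
  arms <- data.frame(
    group = c("intervention", "self_care"),
    expected_cost_payer = vapply(res$arms, function(a) a$cost_payer, 0)[c(1, 2)],
    expected_cost_societal = vapply(res$arms, function(a) a$cost_societal, 0)[c(1, 2)],
    expected_qalys = vapply(res$arms, function(a) a$qalys, 0)[c(1, 2)])
  arms_path <- file.path(dir, "base_case_arms.csv")
  utils::write.csv(arms, arms_path, row.names = FALSE)
  report <- list(
    arms = arms,
    incremental = list(cost_payer = ce$inc_cost, effect_qalys = ce$inc_effect,
                       icer_jpy_per_qaly = if (is.na(ce$icer)) "undefined" else ce$icer,
                       cost_effective_at_wtp = ce$cost_effective, wtp = ce$wtp),
    societal = list(smv = ce$smv,
                    opportunity_cost_saved = ce$smv_opportunity_saved,
                    full_direct_cost_consumed = ce$smv_direct_consumed),
    endo_reduction_percent = res$endo_reduction,
    calibration = if (!is.null(res$calibration))
      list(par = as.list(res$calibration$par),
           objective = res$calibration$objective,
           converged = res$calibration$converged))
  json_path <- file.path(dir, "base_case.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  trace_paths <- vapply(names(res$arms), function(nm) {
    write_trace_csv(res$arms[[nm]]$trace, file.path(dir, paste0("trace_", nm, ".csv")))
  }, character(1))
  files <- c(arms_path, json_path, trace_paths)
  write_manifest(dir, files, seed = seed, params = res$params)
  invisible(files)
}

#' Write PSA report artifacts
#'
#' Per-draw CSV, CEAC CSV and a summary JSON including the acceptance
#' fractions at the 100,000 and 5,000,000 JPY/QALY thresholds.
#'
#' @param psa A `psa_result`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_psa_report <- function(psa, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws_path <- file.path(dir, "psa_draws.csv")
  utils::write.csv(psa$draws, draws_path, row.names = FALSE)
  cc <- ceac(psa)
  ceac_path <- file.path(dir, "ceac.csv")
  utils::write.csv(as.data.frame(cc), ceac_path, row.names = FALSE)
  s <- psa_summary(psa)
  acc <- function(l) mean(l * psa$draws$inc_effect - psa$draws$inc_cost > 0)
  summary_path <- file.path(dir, "psa_summary.json")
  jsonlite::write_json(
    list(n = psa$n, seed = psa$seed,
         inc_cost = as.list(s$inc_cost), inc_effect = as.list(s$inc_effect),
         acceptance_at_100k = acc(1e5), acceptance_at_5M = acc(5e6)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(draws_path, ceac_path, summary_path)
  write_manifest(dir, files, seed = psa$seed)
  invisible(files)
}

#' Run manifest
#'
#' Records the configuration digest, seed, package version, timestamp and
#' output file list for a run, so identical configurations are recognisable
#' and outputs auditable.
#'
#' @param dir Output directory.
#' @param files Character vector of files the run wrote.
#' @param seed Seed used (or `NA`).
#' @param params Optional parameter set; digested via its canonical YAML
#'   serialisation.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, files, seed = NA, params = NULL) {
  digest <- NA_character_
  if (!is.null(params)) {
    tmp <- tempfile(fileext = ".yml")
    on.exit(unlink(tmp))
    write_parameters(params, tmp)
    digest <- unname(tools::md5sum(tmp))
  }
  manifest <- list(package = "endocea",
                   version = as.character(utils::packageVersion("endocea")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, config_digest = digest,
                   outputs = basename(files))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
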