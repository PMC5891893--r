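#' Load model configuration from a YAML file
#'
#' The configuration has up to four sections: `model:`, `costs:`,
#' `distributions:` and `run:`. Scalar entries override base-case values;
#' age schedules are written as mappings with `ages` and `values` (and an
#' optional `interpolation`); the life table as `age`/`qx` vectors. Keys
#' not present fall back to the base case (logged via [message()]); unknown
#' keys are rejected by name; out-of-domain values raise validation errors.
#'
#' @param path Path to a YAML configuration file.
#' @param quiet Suppress the fallback log messages.
#' @return A list with `model`, `cost`, `distributions` and `run`
#'   (`run` holds `seed`, `horizon`, `n_psa`, `wtp`).
#' @seealso [write_parameters()] for the inverse; the two round-trip.
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("configuration parse failure in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(cfg)) cfg <- list()
  known_sections <- c("model", "costs", "distributions", "run")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown)) {
    stop(sprintf("unknown configuration section(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  base <- base_case_parameters()

  mp <- .apply_overrides(base$model, cfg$model, "model",
                         schedule_fields = c("incidence_dysmenorrhea",
                                             "visit_prop_dys", "visit_prop_endo"),
                         quiet = quiet)
  cp <- .apply_overrides(base$cost, cfg$costs, "costs", schedule_fields = character(),
                         quiet = quiet)
  validate_parameters(mp)
  validate_parameters(cp)

  dists <- base$distributions
  for (nm in names(cfg$distributions)) {
    if (!nm %in% names(dists)) {
      stop(sprintf("unknown configuration key: distributions.%s", nm), call. = FALSE)
    }
    d <- cfg$distributions[[nm]]
    dists[[nm]] <- distribution_spec(
      family = d$family %||% dists[[nm]]$family,
      central = d$central %||% dists[[nm]]$central,
      low = d$low %||% dists[[nm]]$low,
      high = d$high %||% dists[[nm]]$high,
      cv = d$cv %||% dists[[nm]]$cv,
      domain = unlist(d$domain %||% dists[[nm]]$domain))
  }

  run_defaults <- list(seed = 20180410, horizon = mp$horizon, n_psa = 10000,
                       wtp = 5e6)
  run <- utils::modifyList(run_defaults, as.list(cfg$run %||% list()))
  unknown_run <- setdiff(names(run), names(run_defaults))
  if (length(unknown_run)) {
    stop(sprintf("unknown configuration key: run.%s", unknown_run[1]), call. = FALSE)
  }
  mp$horizon <- run$horizon
  validate_parameters(mp)
  list(model = mp, cost = cp, distributions = dists, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.apply_overrides <- function(obj, overrides, section, schedule_fields, quiet) {
  fields <- setdiff(names(obj), "life_table")
  missing_keys <- setdiff(fields, names(overrides))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% c(names(obj), "life_table")) {
        stop(sprintf("unknown configuration key: %s.%s", section, nm), call. = FALSE)
      }
      v <- overrides[[nm]]
      if (nm %in% schedule_fields) {
        obj[[nm]] <- age_schedule(unlist(v$ages), unlist(v$values),
                                  v$interpolation %||% "linear")
      } else if (nm == "life_table") {
        df <- data.frame(age = unlist(v$age), qx = unlist(v$qx))
        attr(df, "schedule") <- age_schedule(df$age, df$qx)
        class(df) <- c("life_table", "data.frame")
        obj[[nm]] <- df
      } else {
        obj[[nm]] <- v
      }
    }
  }
  if (!quiet && length(missing_keys) && !is.null(overrides)) {
    message(sprintf("config section `%s`: %d key(s) not set, using base case (%s)",
                    section, length(missing_keys),
                    paste(utils::head(missing_keys, 3), collapse = ", ")))
  }
  obj
}

#' Write a parameter set to a YAML configuration file
#'
#' Serialises a full parameter set (as returned by [base_case_parameters()]
#' or [load_parameters()]) so that `load_parameters(write_parameters(x))`
#' reproduces `x` exactly.
#'
#' @param params List with `model`, `cost` and optionally `distributions`
#'   and `run` components.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  mp <- params$model
  ser_sched <- function(s) list(ages = s$ages, values = s$values,
                                interpolation = s$interpolation)
  model <- list()
  for (nm in names(mp)) {
    model[[nm]] <- if (inherits(mp[[nm]], "age_schedule")) ser_sched(mp[[nm]])
      else if (inherits(mp[[nm]], "life_table")) {
        list(age = mp[[nm]]$age, qx = mp[[nm]]$qx)
      } else mp[[nm]]
  }
  costs <- unclass(params$cost)
  dists <- lapply(params$distributions %||% list(), function(d) {
    out <- list(family = d$family, central = d$central, cv = d$cv,
                domain = d$domain)
    if (!is.null(d$low)) { out$low <- d$low; out$high <- d$high }
    out
  })
  cfg <- list(model = model, costs = costs)
  if (length(dists)) cfg$distributions <- dists
  if (!is.null(params$run)) cfg$run <- params$run
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
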