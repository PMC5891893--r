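#' Synthetic Japanese female life table (ages 12-35 band)
#'
#' The model needs an annual all-cause mortality schedule for young Japanese
#' women. Official life-table values are not redistributable here, so this
#' generator produces a smooth synthetic stand-in with the right order of
#' magnitude: roughly 1e-4 at adolescence rising gently to ~4e-4 by the
#' mid-thirties at `level = 1`. Mortality at these ages is tiny, so results
#' are insensitive to the exact shape (the test suite asserts this).
#'
#' @param start_age,end_age Integer age range covered (inclusive).
#' @param level Scale factor applied to the whole schedule; `0` gives an
#'   all-zero (immortal) table, useful for conservation checks.
#' @return A `life_table`: data.frame with columns `age` and `qx` (annual
#'   death probability), carrying an [age_schedule()] in attribute
#'   `"schedule"`.
#' @examples
#' lt <- make_life_table()
#' head(lt)
#' @export
make_life_table <- function(start_age = 12, end_age = 60, level = 1) {
  stopifnot(start_age < end_age, level >= 0)
  age <- seq(start_age, end_age)
  # Gompertz-like gentle rise; ~1.0e-4 at 12, ~2.1e-4 at 25, ~4.3e-4 at 35.
  qx <- level * (8e-5 + 2.2e-5 * exp(0.105 * (age - 12)))
  qx <- pmin(qx, 0.99)
  out <- data.frame(age = age, qx = qx)
  attr(out, "schedule") <- age_schedule(age, qx)
  attr(out, "synthetic") <- TRUE
  class(out) <- c("life_table", "data.frame")
  out
}

#' Annual death probability at given ages
#'
#' @param lt A `life_table` (see [make_life_table()] or [read_life_table()]).
#' @param age Ages in years.
#' @return Annual all-cause death probabilities (clamped outside the table).
#' @export
mortality_at <- function(lt, age) {
  sched <- attr(lt, "schedule")
  if (is.null(sched)) sched <- age_schedule(lt$age, lt$qx)
  schedule_value(sched, age)
}

#' Read a life table from CSV
#'
#' Schema: columns `age`, `qx`. Users can substitute an official life table
#' for the synthetic default with the same schema.
#' @param path CSV file path.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) {
    stop("read_life_table(): CSV must have columns `age` and `qx`", call. = FALSE)
  }
  if (any(df$qx < 0 | df$qx > 1)) stop("read_life_table(): qx out of [0, 1]", call. = FALSE)
  attr(df, "schedule") <- age_schedule(df$age, df$qx)
  class(df) <- c("life_table", "data.frame")
  df
}

#' Synthetic female population counts by age group
#'
#' Prevalence scaling (counts of endometriosis cases nationwide) needs female
#' population denominators by age. This generator allocates a national total
#' across 5-year age groups nearly uniformly — a deliberate, clearly-labelled
#' approximation of the Japanese female population pyramid at reproductive
#' ages, where single-year cohort sizes are similar (~0.6 million).
#'
#' @param age_groups Data frame with columns `age_low`, `age_high`
#'   (inclusive integer bounds), or `NULL` for the default 10-39 range in
#'   5-year groups.
#' @param total Total female count across all groups (`> 0`). The default
#'   corresponds to ~0.6 million women per single year of age.
#' @return A `population_table`: data.frame with columns `age_low`,
#'   `age_high`, `count`.
#' @export
make_population <- function(age_groups = NULL, total = 18e6) {
  if (!is.numeric(total) || total <= 0) {
    stop("make_population(): `total` must be > 0", call. = FALSE)
  }
  if (is.null(age_groups)) {
    age_groups <- data.frame(age_low = seq(10, 35, by = 5),
                             age_high = seq(14, 39, by = 5))
  }
  stopifnot(all(c("age_low", "age_high") %in% names(age_groups)))
  n_years <- age_groups$age_high - age_groups$age_low + 1
  # Near-uniform: small linear taper with age, then rescale to the total.
  w <- n_years * (1 - 0.006 * (age_groups$age_low - min(age_groups$age_low)))
  count <- total * w / sum(w)
  out <- data.frame(age_low = age_groups$age_low, age_high = age_groups$age_high,
                    count = count)
  attr(out, "synthetic") <- TRUE
  class(out) <- c("population_table", "data.frame")
  out
}

#' Female population count for a single year of age
#'
#' @param pop A `population_table`.
#' @param age Single-year ages.
#' @return Estimated female count at each single year of age (the group
#'   count divided by the group width). Errors if an age is not covered.
#' @export
population_at <- function(pop, age) {
  idx <- vapply(age, function(a) {
    i <- which(pop$age_low <= a & a <= pop$age_high)
    if (length(i) != 1L) {
      stop(sprintf("population_at(): age %s not covered by the population table", a),
           call. = FALSE)
    }
    i
  }, integer(1))
  pop$count[idx] / (pop$age_high[idx] - pop$age_low[idx] + 1)
}

#' Simulate a VAS utility survey
#'
#' Emulates an institution-based cross-sectional survey in which patients
#' rate their health on a visual analogue scale anchored at death (0.000)
#' and perfect health (1.000), by disease stage. Draws are normal around the
#' stage mean, truncated to `[0, 1]` by resampling.
#'
#' @param n Respondents per stage (scalar or vector matching `means`).
#' @param means Named numeric vector of stage means in `[0, 1]`; the default
#'   uses the early-stage (I/II) and advanced-stage (III/IV) endometriosis
#'   means of the base case.
#' @param sd Common rating standard deviation.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `sample` (data.frame: `stage`, `vas`) and
#'   `mean_by_stage` (named numeric).
#' @export
simulate_vas_survey <- function(n = 500,
                                means = c(endo_1_2 = 0.637, endo_3_4 = 0.549),
                                sd = 0.15, seed = 1L) {
  stopifnot(all(n >= 1), all(means >= 0 & means <= 1), sd >= 0)
  n <- rep(n, length.out = length(means))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample <- do.call(rbind, lapply(seq_along(means), function(i) {
    x <- stats::rnorm(n[i], means[i], sd)
    bad <- x < 0 | x > 1
    while (any(bad)) {  # truncation by resampling keeps the mean near target
      x[bad] <- stats::rnorm(sum(bad), means[i], sd)
      bad <- x < 0 | x > 1
    }
    data.frame(stage = names(means)[i], vas = x)
  }))
  mbs <- vapply(split(sample$vas, sample$stage), mean, numeric(1))[names(means)]
  list(sample = sample, mean_by_stage = mbs)
}

# Save/restore the global RNG state so generators are polite library citizens.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write the synthetic fixtures to CSV
#'
#' Writes `life_table.csv` (age, qx) and `population.csv`
#' (age_low, age_high, count) so that users can inspect or replace them with
#' official statistics using the same schema.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lt_path <- file.path(dir, "life_table.csv")
  pop_path <- file.path(dir, "population.csv")
  utils::write.csv(as.data.frame(make_life_table()), lt_path, row.names = FALSE)
  utils::write.csv(as.data.frame(make_population()), pop_path, row.names = FALSE)
  invisible(c(lt_path, pop_path))
}
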