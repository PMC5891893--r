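#' Age-dependent probability schedule
#'
#' Several model inputs (dysmenorrhea incidence, care-seeking proportions,
#' mortality) are printed only as an age range, so they are represented as a
#' small set of `(age, value)` anchors with an interpolation rule. Evaluation
#' clamps outside the anchored range, i.e. the first/last anchor value is
#' carried beyond the ends.
#'
#' @param ages Strictly increasing numeric vector of anchor ages (years).
#' @param values Probabilities per year at each anchor, in `[0, 1]`.
#' @param interpolation `"linear"` (piecewise linear, default) or `"step"`
#'   (left-continuous step function).
#' @return An object of class `age_schedule`.
#' @examples
#' inc <- age_schedule(c(12, 30), c(0.0008, 0.007))
#' schedule_value(inc, c(12, 21, 40))
#' @export
age_schedule <- function(ages, values, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.numeric(ages), is.numeric(values), length(ages) == length(values),
            length(ages) >= 1)
  if (any(diff(ages) <= 0)) {
    stop("age_schedule(): anchor ages must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    stop("age_schedule(): anchor values must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(ages = as.numeric(ages), values = as.numeric(values),
                 interpolation = interpolation),
            class = "age_schedule")
}

#' Evaluate an age schedule
#'
#' @param s An [age_schedule()].
#' @param age Age(s) in years, `>= 0`. Vectorised.
#' @return Probabilities at the requested ages, clamped to the anchor range.
#' @export
schedule_value <- function(s, age) {
  stopifnot(inherits(s, "age_schedule"), is.numeric(age), all(age >= 0))
  if (length(s$ages) == 1L) return(rep(s$values, length.out = length(age)))
  if (s$interpolation == "linear") {
    stats::approx(s$ages, s$values, xout = age, rule = 2, ties = "ordered")$y
  } else {
    stats::approx(s$ages, s$values, xout = age, rule = 2, method = "constant",
                  f = 0, ties = "ordered")$y
  }
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule: %d anchors, %s interpolation>\n",
              length(x$ages), x$interpolation))
  print(data.frame(age = x$ages, value = x$values), row.names = FALSE)
  invisible(x)
}

#' @export
format.age_schedule <- function(x, ...) {
  paste0("age_schedule(", paste(sprintf("%g:%g", x$ages, x$values), collapse = ", "), ")")
}

# Internal: a schedule holding one constant value everywhere.
constant_schedule <- function(value) age_schedule(12, value)
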