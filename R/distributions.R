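#' Uncertainty distribution specification for one parameter
#'
#' Describes how a parameter is sampled in the probabilistic sensitivity
#' analysis. Dispersion can be supplied either as a `(low, high)` range
#' interpreted as a central 95% interval, or as a coefficient of variation
#' (`cv`, defaulting to 0.2) about the central value when no published range
#' exists. Families:
#' \describe{
#'   \item{beta}{moments matched to the central value and the 95% range.}
#'   \item{normal}{mean = central; sd from the range or `cv * central`.}
#'   \item{lognormal}{median-preserving when a range is given
#'     (`meanlog = log(central)`, `sdlog` from the log-range); mean-preserving
#'     when only a `cv` is given.}
#'   \item{fixed}{degenerate; always returns the central value.}
#' }
#' Samples are truncated to `domain` by resampling (at most a handful of
#' iterations in practice since ranges are narrow).
#'
#' @param family One of `"beta"`, `"normal"`, `"lognormal"`, `"fixed"`.
#' @param central Base-case value.
#' @param low,high Optional central 95% interval.
#' @param cv Coefficient of variation used when no interval is given.
#' @param domain Length-2 numeric truncation bounds.
#' @return A `distribution_spec` object.
#' @export
distribution_spec <- function(family = c("beta", "normal", "lognormal", "fixed"),
                              central, low = NULL, high = NULL, cv = 0.2,
                              domain = c(-Inf, Inf)) {
  family <- match.arg(family)
  stopifnot(is.numeric(central), length(central) == 1L)
  if (!is.null(low) || !is.null(high)) {
    stopifnot(is.numeric(low), is.numeric(high), low < high)
  }
  if (family == "beta" && (central < 0 || central > 1)) {
    stop("distribution_spec(): beta central value must be in [0, 1]", call. = FALSE)
  }
  if (family == "lognormal" && central <= 0) {
    stop("distribution_spec(): lognormal central value must be positive", call. = FALSE)
  }
  structure(list(family = family, central = central, low = low, high = high,
                 cv = cv, domain = domain),
            class = "distribution_spec")
}

#' @export
print.distribution_spec <- function(x, ...) {
  disp <- if (!is.null(x$low)) sprintf("95%% (%g, %g)", x$low, x$high)
          else sprintf("cv %.2f", x$cv)
  cat(sprintf("<distribution_spec: %s, central %g, %s>\n", x$family, x$central,
              if (x$family == "fixed") "no dispersion" else disp))
  invisible(x)
}

# Standard-deviation implied by a central 95% interval.
.sd_from_interval <- function(low, high) (high - low) / (2 * stats::qnorm(0.975))

#' Draw from a distribution specification
#'
#' @param spec A [distribution_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, truncated to the spec's domain.
#'   Uses the current RNG stream; seed management belongs to the caller
#'   (see [run_psa()]).
#' @export
sample_spec <- function(spec, n = 1) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  draw <- switch(spec$family,
    fixed = function(k) rep(spec$central, k),
    beta = {
      m <- spec$central
      s <- if (!is.null(spec$low)) .sd_from_interval(spec$low, spec$high)
           else spec$cv * m
      v <- min(s^2, 0.95 * m * (1 - m))  # keep moment matching feasible
      if (v <= 0) function(k) rep(m, k) else {
        a <- m * (m * (1 - m) / v - 1)
        b <- (1 - m) * (m * (1 - m) / v - 1)
        function(k) stats::rbeta(k, a, b)
      }
    },
    normal = {
      s <- if (!is.null(spec$low)) .sd_from_interval(spec$low, spec$high)
           else spec$cv * abs(spec$central)
      function(k) stats::rnorm(k, spec$central, s)
    },
    lognormal = {
      if (!is.null(spec$low)) {
        sdlog <- (log(spec$high) - log(spec$low)) / (2 * stats::qnorm(0.975))
        meanlog <- log(spec$central)            # median-preserving
      } else {
        sdlog <- sqrt(log(1 + spec$cv^2))
        meanlog <- log(spec$central) - sdlog^2 / 2  # mean-preserving
      }
      function(k) stats::rlnorm(k, meanlog, sdlog)
    })
  x <- draw(n)
  bad <- x < spec$domain[1] | x > spec$domain[2]
  tries <- 0L
  while (any(bad) && tries < 1000L) {
    x[bad] <- draw(sum(bad))
    bad <- x < spec$domain[1] | x > spec$domain[2]
    tries <- tries + 1L
  }
  if (any(bad)) x[bad] <- pmin(pmax(x[bad], spec$domain[1]), spec$domain[2])
  x
}

#' Base-case PSA distribution set
#'
#' One [distribution_spec()] per parameter that carries a distribution in
#' the source tables. Published 95% intervals are used where they exist
#' (the one-way ranges of the deterministic sensitivity analysis and the
#' trial confidence intervals for the two risk-reduction ratios); all unit
#' costs use a lognormal with a 0.2 coefficient of variation. The advanced-
#' disease utility interval is taken symmetric on its published upper
#' offset, because its published lower endpoint is an explicit worst-case
#' scenario value rather than a confidence bound. Cure probabilities, the
#' calibrated progression probability, age-dependent schedules and the
#' discount rate are treated as fixed model assumptions and are not
#' sampled.
#'
#' @return Named list of `distribution_spec` objects, names matching
#'   [model_parameters()] / [cost_parameters()] fields.
#' @export
base_case_distributions <- function() {
  p01 <- c(0, 1)
  pos <- c(0, Inf)
  list(
    p_progress_dys_to_endo12 = distribution_spec("beta", 0.184,
                                                 low = 0.179, high = 0.189, domain = p01),
    p_recurrence = distribution_spec("beta", 0.222,
                                     low = 0.206, high = 0.239, domain = p01),
    p_surgery_endo = distribution_spec("normal", 0.06, domain = p01),
    prop_otc_selfcare = distribution_spec("normal", 0.871, domain = p01),
    # risk-reduction ratios: truncated at 1 (a draw above 1 would assert harm
    # and can push competing exits from the dysmenorrhea state past unity)
    or_develop_endo12 = distribution_spec("lognormal", 0.40,
                                          low = 0.2, high = 0.7, domain = p01),
    or_progress_endo34 = distribution_spec("lognormal", 0.10,
                                           low = 1 / 31.17, high = 1 / 3.21,
                                           domain = p01),
    u_dys = distribution_spec("lognormal", 0.637, low = 0.63, high = 0.644,
                              domain = p01),
    u_endo12 = distribution_spec("lognormal", 0.637, low = 0.63, high = 0.644,
                                 domain = p01),
    u_endo34 = distribution_spec("lognormal", 0.549, low = 0.541, high = 0.557,
                                 domain = p01),
    visit_cost_dys = distribution_spec("lognormal", 7529, domain = pos),
    visit_cost_endo = distribution_spec("lognormal", 11291, domain = pos),
    inpatient_cost_annual = distribution_spec("lognormal", 207661, domain = pos),
    surgery_cost_mild = distribution_spec("lognormal", 288080, domain = pos),
    surgery_cost_complex = distribution_spec("lognormal", 456667, domain = pos),
    prop_complex = distribution_spec("lognormal", 0.452, domain = p01),
    otc_cost_annual = distribution_spec("lognormal", 19243, domain = pos),
    selfmed_cost_annual = distribution_spec("lognormal", 13715, domain = pos),
    productivity_loss_halfyear_selfcare =
      distribution_spec("lognormal", 184625, domain = pos),
    productivity_loss_halfyear_intervention =
      distribution_spec("lognormal", 39546, domain = pos)
  )
}
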