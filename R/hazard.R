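#' Convert an instantaneous event rate to a cycle transition probability
#'
#' Under a constant-hazard (exponential) survival assumption, the probability
#' that an event with instantaneous rate `r` per year occurs within `t` years
#' is `p = 1 - exp(-r * t)`. This is the standard conversion used to turn
#' literature rates into yearly Markov transition probabilities.
#'
#' @param r Instantaneous event rate per year (numeric, `>= 0`). Vectorised.
#' @param t Exposure time in years (`> 0`). Defaults to one model cycle.
#' @return Transition probability in `[0, 1)`.
#' @seealso [prob_to_rate()], [apply_odds_ratio()]
#' @examples
#' rate_to_prob(0.2032)        # ~0.184
#' rate_to_prob(0, 1)          # exactly 0
#' @export
rate_to_prob <- function(r, t = 1) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(r < 0)) stop("rate_to_prob(): rate `r` must be non-negative", call. = FALSE)
  if (any(t <= 0)) stop("rate_to_prob(): time `t` must be positive", call. = FALSE)
  1 - exp(-r * t)
}

#' Convert a cycle transition probability to an instantaneous rate
#'
#' Exact inverse of [rate_to_prob()]: `r = -log(1 - p) / t`, assuming the
#' event follows an exponential (constant-hazard) survival distribution.
#'
#' @param p Probability in `[0, 1)`. Vectorised.
#' @param t Exposure time in years (`> 0`).
#' @return Rate per year (`>= 0`).
#' @examples
#' prob_to_rate(0.184)   # ~0.2032
#' @export
prob_to_rate <- function(p, t = 1) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(p < 0) || any(p >= 1)) {
    stop("prob_to_rate(): probability `p` must lie in [0, 1); p = 1 implies an infinite rate",
         call. = FALSE)
  }
  if (any(t <= 0)) stop("prob_to_rate(): time `t` must be positive", call. = FALSE)
  -log(1 - p) / t
}

#' Adjust an annual transition probability by an odds/hazard ratio
#'
#' Implements the risk-reduction adjustment on the hazard scale: the
#' baseline probability is converted to a rate, the rate is multiplied by
#' the ratio (`r_adj = r * or`), and the adjusted rate is converted back to
#' a probability. A ratio below 1 therefore always reduces the probability,
#' and applying two ratios in sequence equals applying their product
#' (hazard multiplicativity).
#'
#' @param p Annual baseline probability in `[0, 1)`.
#' @param or Ratio applied on the hazard scale (`> 0`).
#' @param t Cycle length in years.
#' @return Adjusted annual probability.
#' @examples
#' apply_odds_ratio(0.184, 0.40)  # ~0.0781
#' apply_odds_ratio(0.5, 0.10)    # ~0.0670
#' @export
apply_odds_ratio <- function(p, or, t = 1) {
  if (any(or <= 0)) stop("apply_odds_ratio(): ratio `or` must be positive", call. = FALSE)
  rate_to_prob(prob_to_rate(p, t) * or, t)
}
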