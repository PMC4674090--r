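#' Reward-survival prior
#'
#' Prior probability that a reward opportunity is still available at approach
#' latency `t1`. Reward lifetimes are exponential with rate `lambda1`
#' (1/seconds), so the survival function is `exp(-lambda1 * t1)`.
#'
#' @param lambda1 Reward-disappearance rate in 1/seconds; must be positive.
#'   The default corresponds to a mean token lifetime of 1.25 s.
#' @return An object of class `gain_prior` with analytic value and
#'   derivative functions.
#' @examples
#' gp <- gain_prior(0.8)
#' gp$value(1.25)   # exp(-1)
#' @export
gain_prior <- function(lambda1 = 0.8) {
  stopifnot(is.numeric(lambda1), length(lambda1) == 1L, lambda1 > 0)
  obj <- list(
    lambda1 = lambda1,
    value = function(t1) {
      if (any(t1 < 0)) stop("gain probability undefined for negative latency")
      exp(-lambda1 * t1)
    },
    d1 = function(t1) -lambda1 * exp(-lambda1 * t1),
    d2 = function(t1) lambda1^2 * exp(-lambda1 * t1)
  )
  class(obj) <- "gain_prior"
  obj
}

#' Exposure-only threat model (scenario 1)
#'
#' Threat model matching the objective task statistics: the punisher
#' activates as a homogeneous Poisson process with rate `lambda2` while the
#' agent is exposed, so the loss probability depends on the exposure
#' duration only, never on the approach latency.
#'
#' @param lambda2 Threat activation rate in 1/seconds; must be positive.
#' @return An object of class `threat_scenario1`.
#' @seealso [rate_from_catch_probability()] to derive `lambda2` from a
#'   design catch probability.
#' @export
threat_scenario1 <- function(lambda2) {
  stopifnot(is.numeric(lambda2), length(lambda2) == 1L, lambda2 > 0)
  structure(list(lambda2 = lambda2), class = "threat_scenario1")
}

#' General time-dependent threat prior
#'
#' A subjective prior on the probability of loss as a function of approach
#' latency `t1`, with analytic first and second derivatives. This is the
#' scenario-2 ingredient: threat probability is high just after a reward
#' appears and decays afterwards, reflecting a temporal correlation between
#' reward occurrence and predatory threat.
#'
#' @param value Vectorised function `t1 -> probability`.
#' @param d1,d2 Vectorised first and second derivatives of `value`.
#' @param support Numeric length-2 vector, the latency interval (seconds) on
#'   which the prior is defined.
#' @param check Logical; verify on a grid that values lie in \[0, 1\].
#' @return An object of class `threat_prior`.
#' @export
threat_prior <- function(value, d1, d2, support = c(0, 5), check = TRUE) {
  stopifnot(is.function(value), is.function(d1), is.function(d2),
            length(support) == 2L, support[2] > support[1], support[1] >= 0)
  if (check) {
    tt <- seq(support[1], support[2], length.out = 201L)
    v <- value(tt)
    if (any(!is.finite(v)) || any(v < -1e-9) || any(v > 1 + 1e-9))
      stop("threat prior values outside [0, 1] on the stated support")
  }
  structure(list(value = value, d1 = d1, d2 = d2, support = support),
            class = "threat_prior")
}

#' Clamped-quadratic threat prior
#'
#' The package's canonical parametric scenario-2 prior: the derivative of the
#' loss probability is linear in latency, `d(t) = d0 + slope * t`, clamped at
#' zero from above (the prior can only decay). Integrating gives a quadratic
#' decay that flattens to a constant baseline once the derivative reaches
#' zero. The additive constant is fixed by anchoring: the prior passes
#' through probability `anchor_p` at latency `anchor_t`.
#'
#' This is the same three-parameter family produced by [fit_prior()] /
#' [reconstruct_prior()], so simulated agents driven by it admit an exact
#' forward-inverse round trip.
#'
#' @param d0 Derivative intercept (1/seconds); must be negative.
#' @param slope Derivative slope (1/seconds^2); non-negative (a negative
#'   slope never unclamps, so the prior would eventually leave \[0,1\]).
#' @param anchor_t,anchor_p Anchor point: `value(anchor_t) == anchor_p`.
#' @param t_max Upper end of the support (seconds).
#' @return An object of class `c("quadratic_threat_prior", "threat_prior")`
#'   carrying the parameters alongside the functional interface.
#' @examples
#' pr <- quadratic_threat_prior(-0.9, 0.6, anchor_t = 1, anchor_p = 0.25)
#' pr$value(c(0, 0.5, 1, 2))
#' @export
quadratic_threat_prior <- function(d0, slope, anchor_t, anchor_p,
                                   t_max = 5) {
  stopifnot(d0 < 0, slope >= 0, anchor_t >= 0, anchor_t <= t_max,
            anchor_p >= 0, anchor_p <= 1)
  t_root <- if (slope > 0) -d0 / slope else Inf

  # integral of the clamped derivative min(d0 + slope t, 0) from 0 to t
  int_d <- function(t) {
    tc <- pmin(t, t_root)
    d0 * tc + slope * tc^2 / 2
  }
  p0 <- anchor_p - int_d(anchor_t)
  value <- function(t1) p0 + int_d(t1)
  d1 <- function(t1) pmin(d0 + slope * t1, 0)
  d2 <- function(t1) ifelse(t1 < t_root, slope, 0)

  obj <- threat_prior(value, d1, d2, support = c(0, t_max))
  obj$pars <- c(d0 = d0, slope = slope, p0 = p0)
  obj$t_root <- t_root
  class(obj) <- c("quadratic_threat_prior", class(obj))
  obj
}

#' Scale a threat prior's loss probability
#'
#' Returns the prior with its loss probability multiplied by `k`, capped at
#' probability 1. Where the cap binds the derivatives are zero. Used both for
#' the comparative-statics perturbation ("overall probability of loss
#' increases") and for mapping a mean-threat baseline prior to an individual
#' threat level.
#'
#' @param prior A `threat_prior`.
#' @param k Positive scale factor.
#' @return A `threat_prior` with scaled value/derivatives; attribute
#'   `scale_k` records the factor.
#' @export
scale_threat_prior <- function(prior, k) {
  stopifnot(inherits(prior, "threat_prior"), is.numeric(k), k > 0)
  base <- prior
  value <- function(t1) pmin(k * base$value(t1), 1)
  d1 <- function(t1) ifelse(k * base$value(t1) < 1, k * base$d1(t1), 0)
  d2 <- function(t1) ifelse(k * base$value(t1) < 1, k * base$d2(t1), 0)
  obj <- threat_prior(value, d1, d2, support = base$support, check = FALSE)
  obj$scale_k <- k
  obj$parent <- base
  obj
}

# TRUE if min(k * value, 1) caps anywhere on a grid over the interval
prior_cap_binds <- function(prior, k, interval, n = 501L) {
  tt <- seq(interval[1], interval[2], length.out = n)
  any(k * prior$value(tt) > 1)
}
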