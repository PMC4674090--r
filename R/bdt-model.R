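#' Probability that the reward is still available
#'
#' Survival probability of an exponentially distributed reward lifetime at
#' approach latency `t1`.
#'
#' @param t1 Approach latency in seconds (non-negative, vectorised).
#' @param prior A [gain_prior()].
#' @return Probability `exp(-lambda1 * t1)`.
#' @export
gain_probability <- function(t1, prior) {
  stopifnot(inherits(prior, "gain_prior"))
  if (any(t1 < 0)) stop("approach latency must be non-negative")
  prior$value(t1)
}

#' Probability of punishment under the objective task statistics
#'
#' Under a homogeneous Poisson activation process the probability of at
#' least one punisher activation during an exposure of duration `delta_t`
#' is `1 - exp(-lambda2 * delta_t)`, independent of when the exposure
#' starts.
#'
#' @param delta_t Exposure duration in seconds (non-negative, vectorised).
#' @param model A [threat_scenario1()].
#' @return Activation probability.
#' @export
loss_probability_scenario1 <- function(delta_t, model) {
  stopifnot(inherits(model, "threat_scenario1"))
  if (any(delta_t < 0)) stop("exposure duration must be non-negative")
  1 - exp(-model$lambda2 * delta_t)
}

#' Poisson rate implied by a per-exposure catch probability
#'
#' Inverts the exposure-duration loss probability: a design that prescribes
#' catch probability `p` over an exposure of `delta_t` seconds implies an
#' activation rate `-log(1 - p) / delta_t`.
#'
#' @param p Catch probability per exposure, in (0, 1) (vectorised).
#' @param delta_t Exposure duration in seconds (> 0).
#' @return Rate in 1/seconds.
#' @examples
#' rate_from_catch_probability(c(0.1, 0.2, 0.3), 0.1)
#' @export
rate_from_catch_probability <- function(p, delta_t) {
  if (any(p <= 0 | p >= 1)) stop("catch probability must lie strictly in (0, 1)")
  if (delta_t <= 0) stop("exposure duration must be positive")
  -log(1 - p) / delta_t
}

#' Bayesian decision model of approach latency
#'
#' Constructs the expected-utility model for a single approach decision. The
#' agent gains utility `G` if it reaches the reward before it disappears and
#' incurs utility `L` (negative) if the punisher activates. With no sensory
#' information about the outcome, both probabilities are priors:
#' the gain prior is the reward-lifetime survival function, and the threat
#' side is either the exposure-only scenario-1 model (loss probability
#' independent of approach latency) or a time-dependent scenario-2
#' [threat_prior()] whose loss probability decays with latency. The planned
#' exposure duration `exposure` is fixed independently of the approach
#' latency, so only the latency dependence enters the optimisation.
#'
#' An optional motor cost `c(t1) = c0 * exp(-r * t1)` can be added: urgency
#' of movement is costly, and the cost relaxes with latency. This term
#' creates a non-trivial optimum even under scenario 1, but one that is
#' insensitive to threat — the property that empirically separates motor
#' cost from a threat prior.
#'
#' @param G Utility of the gain (> 0).
#' @param L Utility of the loss (< 0).
#' @param gain A [gain_prior()].
#' @param threat A [threat_scenario1()] or [threat_prior()].
#' @param exposure Planned exposure duration in seconds (used only by
#'   scenario-1 threat models).
#' @param motor_cost Optional list with elements `c0` (>= 0) and `r` (> 0).
#' @return An object of class `bdt_model`.
#' @examples
#' m <- bdt_model(G = 1, L = -2, gain = gain_prior(0.8),
#'                threat = quadratic_threat_prior(-0.9, 0.6, 1, 0.25))
#' optimal_latency(m)
#' @export
bdt_model <- function(G, L, gain = gain_prior(), threat,
                      exposure = 0.1, motor_cost = NULL) {
  stopifnot(is.numeric(G), length(G) == 1L, G > 0,
            is.numeric(L), length(L) == 1L, L < 0,
            inherits(gain, "gain_prior"),
            inherits(threat, "threat_scenario1") || inherits(threat, "threat_prior"),
            is.numeric(exposure), exposure >= 0)
  if (!is.null(motor_cost)) {
    stopifnot(is.list(motor_cost), motor_cost$c0 >= 0, motor_cost$r > 0)
  }
  structure(list(G = G, L = L, gain = gain, threat = threat,
                 exposure = exposure, motor_cost = motor_cost),
            class = "bdt_model")
}

#' @export
print.bdt_model <- function(x, ...) {
  scen <- if (inherits(x$threat, "threat_scenario1")) {
    sprintf("scenario 1 (exposure-only hazard, lambda2 = %.4g/s)",
            x$threat$lambda2)
  } else "scenario 2 (time-dependent threat prior)"
  cat("Bayesian decision model of approach latency\n")
  cat(sprintf("  gain utility G = %.3g, loss utility L = %.3g\n", x$G, x$L))
  cat(sprintf("  reward-disappearance rate lambda1 = %.4g/s\n", x$gain$lambda1))
  cat(sprintf("  threat: %s\n", scen))
  if (!is.null(x$motor_cost))
    cat(sprintf("  motor cost: %.3g * exp(-%.3g * t1)\n",
                x$motor_cost$c0, x$motor_cost$r))
  invisible(x)
}

threat_support <- function(model) {
  if (inherits(model$threat, "threat_prior")) model$threat$support else c(0, Inf)
}

# loss probability as a function of approach latency
model_loss_prob <- function(model, t1) {
  if (inherits(model$threat, "threat_scenario1")) {
    rep(loss_probability_scenario1(model$exposure, model$threat), length(t1))
  } else {
    model$threat$value(t1)
  }
}

#' Expected utility of approaching at latency `t1`
#'
#' `Z(t1) = P_L(t1) * L + P_G(t1) * G - c(t1)`, the expected utility of the
#' movement; the motor-cost term is present only when the model carries one.
#'
#' @param t1 Approach latency in seconds (vectorised).
#' @param model A [bdt_model()].
#' @return Expected utility.
#' @export
expected_utility <- function(t1, model) {
  stopifnot(inherits(model, "bdt_model"))
  sup <- threat_support(model)
  if (any(t1 < sup[1] | t1 > sup[2]))
    stop("approach latency outside the threat prior's support")
  z <- model_loss_prob(model, t1) * model$L +
    gain_probability(t1, model$gain) * model$G
  if (!is.null(model$motor_cost))
    z <- z - model$motor_cost$c0 * exp(-model$motor_cost$r * t1)
  z
}

#' Analytic derivative of expected utility
#'
#' Uses the priors' analytic derivatives; for scenario-1 threat models the
#' loss term is constant in latency and only the gain term contributes,
#' `-G * lambda1 * exp(-lambda1 * t1)`.
#'
#' @inheritParams expected_utility
#' @return dZ/dt1 in utility per second.
#' @export
utility_derivative <- function(t1, model) {
  stopifnot(inherits(model, "bdt_model"))
  sup <- threat_support(model)
  if (any(t1 < sup[1] | t1 > sup[2]))
    stop("approach latency outside the threat prior's support")
  d <- model$gain$d1(t1) * model$G
  if (inherits(model$threat, "threat_prior")) {
    if (!is.function(model$threat$d1))
      stop("threat prior does not provide a derivative")
    d <- d + model$threat$d1(t1) * model$L
  }
  if (!is.null(model$motor_cost))
    d <- d + model$motor_cost$c0 * model$motor_cost$r *
      exp(-model$motor_cost$r * t1)
  d
}

#' Optimal approach latency
#'
#' Maximises expected utility over an interval by dense grid scan followed
#' by bisection on the analytic derivative around the best grid point. When
#' the maximiser sits at an interval endpoint (as it provably does under
#' scenario-1 statistics, where utility strictly decreases in latency) it is
#' returned with `boundary = TRUE`. Among equal-utility optima the smallest
#' latency is returned.
#'
#' @param model A [bdt_model()].
#' @param interval Numeric length-2 search interval in seconds.
#' @param resolution Grid step in seconds (default 1 ms).
#' @return List with `t1` (maximiser, seconds), `utility` (achieved expected
#'   utility), and `boundary` (logical).
#' @export
optimal_latency <- function(model, interval = c(0, 5), resolution = 0.001) {
  stopifnot(inherits(model, "bdt_model"),
            length(interval) == 2L, interval[2] > interval[1],
            interval[1] >= 0, resolution > 0)
  sup <- threat_support(model)
  lo <- max(interval[1], sup[1])
  hi <- min(interval[2], sup[2])
  if (hi <= lo) stop("search interval does not intersect the prior support")

  tt <- seq(lo, hi, by = resolution)
  if (tt[length(tt)] < hi) tt <- c(tt, hi)
  z <- expected_utility(tt, model)
  i <- which.max(z)          # which.max takes the first, i.e. smallest t1
  t_best <- tt[i]

  boundary <- i == 1L || i == length(tt)
  if (!boundary) {
    # refine: the derivative changes sign from + to - inside [t_{i-1}, t_{i+1}]
    f <- function(t) utility_derivative(t, model)
    a <- tt[i - 1L]; b <- tt[i + 1L]
    fa <- f(a); fb <- f(b)
    if (is.finite(fa) && is.finite(fb) && fa > 0 && fb < 0) {
      root <- stats::uniroot(f, lower = a, upper = b, tol = 1e-9)$root
      if (expected_utility(root, model) >= z[i]) t_best <- root
    }
  }
  list(t1 = t_best,
       utility = expected_utility(t_best, model),
       boundary = boundary)
}

#' @describeIn optimal_latency `predict` method returning the optimal
#'   latency of a fitted decision model.
#' @param object A `bdt_model`.
#' @param ... Passed on to `optimal_latency`.
#' @export
predict.bdt_model <- function(object, ...) optimal_latency(object, ...)

#' Check the scenario-2 assumptions on an interval
#'
#' Verifies, on a dense grid over `interval`, the three conditions under
#' which a non-zero interior optimal latency exists: (a7) the threat prior
#' decays (`dP_L/dt1 < 0`); (a8) expected gain decays (`dE(G)/dt1 < 0`);
#' (a9) expected loss initially decays faster than expected gain and
#' asymptotes sooner: the decay rate of the expected loss, `dE(L)/dt1`
#' (positive, since the loss shrinks), exceeds the decay rate of the
#' expected gain, `-dE(G)/dt1`, at the left end of the interval, with the
#' inequality reversed at the right end. Equivalently, the derivative of
#' expected gain and the negated derivative of expected loss cross, which
#' forces a + to - sign change of `dZ/dt1` and hence an interior maximum.
#'
#' @param model A [bdt_model()] with a differentiable threat prior.
#' @param interval Latency interval in seconds.
#' @param n Grid size.
#' @return List of logicals `a7`, `a8`, `a9`.
#' @export
verify_assumptions <- function(model, interval = c(0.05, 2), n = 401L) {
  stopifnot(inherits(model, "bdt_model"))
  tt <- seq(interval[1], interval[2], length.out = n)
  dEG <- model$gain$d1(tt) * model$G
  if (inherits(model$threat, "threat_scenario1")) {
    dPL <- rep(0, n)
  } else {
    dPL <- model$threat$d1(tt)
  }
  dEL <- dPL * model$L
  list(a7 = all(dPL < 0),
       a8 = all(dEG < 0),
       a9 = dEL[1] > -dEG[1] && dEL[n] < -dEG[n])
}

#' Shift of the optimal latency under loss scaling
#'
#' Recomputes the optimal approach latency after inflating either the loss
#' magnitude (`L' = k * L`) or the loss probability (`P_L' = min(k * P_L,
#' 1)`) and returns the signed latency shift `t1' - t1*`. For scenario-2
#' models with an interior maximiser and modest `k`, the shift is
#' non-negative: larger potential loss, or more probable loss, delays the
#' optimal approach. Under scenario-1 statistics (with or without a motor
#' cost) the loss term does not depend on latency, so the shift is exactly
#' zero.
#'
#' @param model A [bdt_model()].
#' @param k Scale factor (> 0; the comparative-statics result concerns
#'   k > 1).
#' @param mode `"loss_magnitude"` or `"loss_probability"`.
#' @param interval,resolution Passed to [optimal_latency()].
#' @return List with `shift` (seconds), `t1_base`, `t1_scaled`, and the two
#'   `optimal_latency` results.
#' @export
latency_shift_under_scaling <- function(model, k,
                                        mode = c("loss_magnitude",
                                                 "loss_probability"),
                                        interval = c(0, 5),
                                        resolution = 0.001) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bdt_model"), is.numeric(k), k > 0)
  base <- optimal_latency(model, interval, resolution)
  scaled_model <- model
  if (mode == "loss_magnitude") {
    scaled_model$L <- k * model$L
  } else {
    if (inherits(model$threat, "threat_scenario1")) {
      p <- loss_probability_scenario1(model$exposure, model$threat)
      if (k * p > 1)
        stop("scaled loss probability exceeds 1")
      # represent the scaled constant hazard through an equivalent rate
      scaled_model$threat <-
        threat_scenario1(rate_from_catch_probability(min(k * p, 1 - 1e-12),
                                                     model$exposure))
    } else {
      sup <- threat_support(model)
      eff <- c(max(interval[1], sup[1]), min(interval[2], sup[2]))
      if (prior_cap_binds(model$threat, k, eff))
        stop("scaled threat prior exceeds probability 1 inside the searched interval")
      scaled_model$threat <- scale_threat_prior(model$threat, k)
    }
  }
  new <- optimal_latency(scaled_model, interval, resolution)
  list(shift = new$t1 - base$t1, t1_base = base$t1, t1_scaled = new$t1,
       base = base, scaled = new)
}
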