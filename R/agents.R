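#' Agent policies for the conflict-game simulator
#'
#' An agent policy bundles the decision rule and latency plan that the
#' simulator consults at each token opportunity. `plan_latency` and
#' `plan_return` give intended latencies (seconds) as a function of the
#' threat level index and the number of tokens already in hand; realised
#' latencies add zero-mean Gaussian noise (sd `latency_noise_sd`),
#' truncated below at zero (approach) or at one activation bin (return). `error_rate` is the probability of moving in the wrong
#' left/right direction, independent of condition.
#'
#' @param decide Function `(level, tokens_in_hand) -> logical`, the go/no-go
#'   choice.
#' @param plan_latency Function `(level, tokens_in_hand) -> seconds`.
#' @param plan_return Function `(level, tokens_in_hand) -> seconds`, the
#'   intended exposure duration.
#' @param latency_noise_sd Gaussian latency noise sd in seconds.
#' @param error_rate Probability of a wrong-direction movement.
#' @param label Short description used in printing.
#' @return An object of class `aac_agent`.
#' @export
aac_agent <- function(decide, plan_latency, plan_return,
                      latency_noise_sd = 0.05, error_rate = 0.028,
                      label = "custom") {
  stopifnot(is.function(decide), is.function(plan_latency),
            is.function(plan_return),
            latency_noise_sd >= 0, error_rate >= 0, error_rate < 1)
  structure(list(decide = decide, plan_latency = plan_latency,
                 plan_return = plan_return,
                 latency_noise_sd = latency_noise_sd,
                 error_rate = error_rate, label = label),
            class = "aac_agent")
}

#' @export
print.aac_agent <- function(x, ...) {
  cat(sprintf("approach-avoidance agent policy: %s\n", x$label))
  cat(sprintf("  latency noise sd = %g s, direction error rate = %g\n",
              x$latency_noise_sd, x$error_rate))
  invisible(x)
}

#' Decision-theoretically optimal agent
#'
#' Builds an agent whose planned approach latency at each (threat level,
#' potential loss) condition is the optimal latency of a [bdt_model()]: the
#' baseline threat prior is scaled by the level's loss-probability factor
#' `level_scales[i]`, and the loss utility is set by `loss_fun(level,
#' tokens_in_hand)` (negative, in token units). The agent goes when the
#' achieved expected utility at the planned latency is positive, unless
#' `always_go = TRUE`.
#'
#' Planned latencies are precomputed for all conditions at construction, so
#' a policy is cheap to evaluate inside the simulator, and deterministic:
#' with zero noise the same condition always yields the same latency.
#'
#' @param prior Baseline (mean-threat) [threat_prior()].
#' @param G Gain utility per token (default 1; all utilities in token
#'   units).
#' @param gain A [gain_prior()].
#' @param noise_sd Latency noise sd in seconds (default 50 ms).
#' @param exposure Planned exposure duration in seconds.
#' @param level_scales Multiplier applied to the baseline prior per threat
#'   level; defaults to the design catch probabilities normalised to mean 1.
#' @param loss_fun Function `(level, tokens_in_hand) -> negative utility`.
#'   The default charges the tokens at stake plus the current opportunity,
#'   `-(tokens_in_hand + 1)`; pass [make_ideal_observer_loss()] for the
#'   opportunity-cost accounting used by the prior reconstruction.
#' @param always_go Logical; collapse the go/no-go rule to always-go
#'   (useful when only the latency plan is under study).
#' @param interval,resolution Passed to [optimal_latency()].
#' @param n_levels,max_tokens Condition grid dimensions to precompute.
#' @param error_rate Wrong-direction probability.
#' @return An `aac_agent` whose `plan` element holds the precomputed
#'   per-condition latency/utility tables.
#' @export
make_bdt_agent <- function(prior, G = 1, gain = gain_prior(0.8),
                           noise_sd = 0.05, exposure = 0.1,
                           level_scales = c(0.1, 0.2, 0.3) / 0.2,
                           loss_fun = function(level, tokens) -(tokens + 1),
                           always_go = FALSE,
                           interval = c(0, 5), resolution = 0.001,
                           n_levels = length(level_scales), max_tokens = 6,
                           error_rate = 0.028) {
  stopifnot(inherits(prior, "threat_prior"), all(level_scales > 0),
            n_levels <= length(level_scales))

  lat <- matrix(NA_real_, n_levels, max_tokens,
                dimnames = list(level = NULL, tokens = NULL))
  util <- lat
  bound <- matrix(NA, n_levels, max_tokens)
  for (i in seq_len(n_levels)) {
    thr <- scale_threat_prior(prior, level_scales[i])
    for (t in seq_len(max_tokens)) {
      L <- loss_fun(i, t - 1L)
      if (!is.finite(L) || L >= 0)
        stop("loss_fun must return a negative utility")
      m <- bdt_model(G = G, L = L, gain = gain, threat = thr,
                     exposure = exposure)
      opt <- optimal_latency(m, interval, resolution)
      lat[i, t] <- opt$t1
      util[i, t] <- opt$utility
      bound[i, t] <- opt$boundary
    }
  }

  agent <- aac_agent(
    decide = if (always_go) function(level, tokens) TRUE
             else function(level, tokens) util[level, tokens + 1L] > 0,
    plan_latency = function(level, tokens) lat[level, tokens + 1L],
    plan_return = function(level, tokens) exposure,
    latency_noise_sd = noise_sd,
    error_rate = error_rate,
    label = if (always_go) "BDT-optimal (always-go)" else "BDT-optimal"
  )
  agent$plan <- list(latency = lat, utility = util, boundary = bound,
                     level_scales = level_scales[seq_len(n_levels)],
                     exposure = exposure, G = G, lambda1 = gain$lambda1)
  agent
}

#' Fixed-latency agent
#'
#' Always goes, with a condition-independent planned latency and exposure.
#'
#' @param latency Planned approach latency in seconds.
#' @param exposure Planned exposure duration in seconds.
#' @param noise_sd,error_rate See [aac_agent()].
#' @return An `aac_agent`.
#' @export
make_fixed_agent <- function(latency = 0.5, exposure = 0.3,
                             noise_sd = 0.05, error_rate = 0.028) {
  aac_agent(decide = function(level, tokens) TRUE,
            plan_latency = function(level, tokens) latency,
            plan_return = function(level, tokens) exposure,
            latency_noise_sd = noise_sd, error_rate = error_rate,
            label = sprintf("fixed latency %g s", latency))
}

#' Random-choice agent
#'
#' Goes with probability `go_prob` independently at each opportunity, with a
#' latency drawn uniformly from `latency_range` (using the simulation RNG
#' stream, hence reproducible under a fixed seed).
#'
#' @param go_prob Go probability per opportunity.
#' @param latency_range Length-2 numeric, uniform latency support (s).
#' @param exposure Planned exposure duration in seconds.
#' @param noise_sd,error_rate See [aac_agent()].
#' @return An `aac_agent`.
#' @export
make_random_agent <- function(go_prob = 0.8, latency_range = c(0.2, 1.5),
                              exposure = 0.3, noise_sd = 0,
                              error_rate = 0.028) {
  stopifnot(go_prob >= 0, go_prob <= 1, length(latency_range) == 2L)
  aac_agent(decide = function(level, tokens) stats::runif(1) < go_prob,
            plan_latency = function(level, tokens)
              stats::runif(1, latency_range[1], latency_range[2]),
            plan_return = function(level, tokens) exposure,
            latency_noise_sd = noise_sd, error_rate = error_rate,
            label = "random")
}

#' Never-go agent
#'
#' Declines every opportunity; useful as a degenerate pipeline input.
#'
#' @return An `aac_agent`.
#' @export
make_never_agent <- function() {
  aac_agent(decide = function(level, tokens) FALSE,
            plan_latency = function(level, tokens) NA_real_,
            plan_return = function(level, tokens) NA_real_,
            latency_noise_sd = 0, error_rate = 0, label = "never-go")
}
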