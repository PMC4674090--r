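#' Example scenario-2 threat priors and agents
#'
#' `example_threat_prior()` returns the package's reference mean-threat
#' prior, a clamped-quadratic decay. Its parameters are the fixed point of
#' a self-consistency calibration under the default task (token lifetime
#' 1.25 s, catch probabilities 0.1/0.2/0.3 per 100 ms): an agent driven by
#' this prior together with `example_observer_params()` produces simulated
#' data whose re-estimated ideal-observer parameters match the assumed
#' ones, and whose mean approach latency sits at the anchoring point
#' (prior value = mean design catch rate 0.2 at 0.74 s). That makes the
#' forward-inverse reconstruction round trip self-consistent.
#'
#' `example_bdt_agent()` assembles the corresponding decision-theoretic
#' agent, pricing each movement with the ideal-observer potential loss.
#' Because the opportunity-cost loss shrinks with the catch probability,
#' its highest threat level carries a small potential loss at zero tokens
#' in hand, and the optimal latency for that single cell collapses to the
#' interval boundary — faithful to the accounting, but that cell then
#' yields no analysable latencies.
#'
#' `simple_bdt_agent()` is a cleaner comparative-statics demonstrator: the
#' loss is the tokens at stake plus a fixed two-token opportunity offset,
#' identical across threat levels, and the prior
#' (`quadratic_threat_prior(-1.2, 1.2, 0.8, 0.05)`) is steep enough that
#' every (threat level, potential loss) condition has an interior optimum
#' well inside the analysable response window. Its simulated latencies are
#' strictly increasing in both threat level and potential loss.
#'
#' @param noise_sd Latency noise sd in seconds.
#' @param always_go Collapse the go/no-go rule to always-go.
#' @param ... Passed on to [make_bdt_agent()].
#' @return A `threat_prior`, an `ideal_observer_params`, or an
#'   `aac_agent`, respectively.
#' @examples
#' agent <- simple_bdt_agent(noise_sd = 0)
#' agent$plan$latency   # planned latency per level x tokens-in-hand
#' @export
example_threat_prior <- function() {
  quadratic_threat_prior(d0 = -1.35, slope = 1.35,
                         anchor_t = 0.74, anchor_p = 0.2, t_max = 5)
}

#' @rdname example_threat_prior
#' @export
example_observer_params <- function() {
  ideal_observer_params(D = c(3.32, 3.23, 3.56),
                        P_C = c(0.1, 0.2, 0.3),
                        P_T = 0.58)
}

#' @rdname example_threat_prior
#' @export
example_bdt_agent <- function(noise_sd = 0.05, always_go = FALSE, ...) {
  pars <- example_observer_params()
  make_bdt_agent(prior = example_threat_prior(),
                 loss_fun = make_ideal_observer_loss(pars),
                 level_scales = 1 / pars$scale_c,
                 noise_sd = noise_sd, always_go = always_go, ...)
}

#' @rdname example_threat_prior
#' @export
simple_bdt_agent <- function(noise_sd = 0.05, always_go = FALSE, ...) {
  make_bdt_agent(prior = quadratic_threat_prior(-1.2, 1.2, anchor_t = 0.8,
                                                anchor_p = 0.05),
                 loss_fun = function(level, tokens) -(tokens + 2),
                 noise_sd = noise_sd, always_go = always_go, ...)
}
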