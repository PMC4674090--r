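#' Configuration of the operant conflict game
#'
#' Collects all parameters of the virtual approach-avoidance game: epochs of
#' up to `tokens_per_epoch` sequential reward tokens with exponential
#' lifetimes, inter-token intervals composed of a carried-over remaining
#' lifetime, a constant part and an exponential part, and a predator whose
#' activation is determined independently in discrete time bins while the
#' player is exposed. Threat levels are specified as catch probabilities per
#' `catch_window` seconds of exposure; the implied Poisson rates follow from
#' [rate_from_catch_probability()].
#'
#' @param n_epochs Epochs per subject (default 270).
#' @param tokens_per_epoch Tokens per epoch (default 6).
#' @param token_lifetime_mean Mean token lifetime in seconds (default
#'   1.25 s).
#' @param iti_constant Constant part of the inter-token interval (s).
#' @param iti_variable_mean Mean of the exponential part of the inter-token
#'   interval (s).
#' @param threat_levels Ascending catch probabilities per `catch_window` of
#'   exposure, one per predator (default 0.1, 0.2, 0.3).
#' @param catch_window Reference exposure duration for `threat_levels`
#'   (default 0.1 s).
#' @param activation_bin Predator activation bin width in seconds (default
#'   20 ms).
#' @param approach_window Open interval of analysable approach latencies (s).
#' @param return_window Interval of analysable return latencies (s); the
#'   lower bound is exclusive.
#' @return An object of class `task_config`. The element `lambda2` holds
#'   the per-level activation rates (1/s) and `lambda1` the reward
#'   disappearance rate.
#' @examples
#' cfg <- task_config()
#' cfg$lambda2   # 1.0536 2.2314 3.5667
#' @export
task_config <- function(n_epochs = 270L,
                        tokens_per_epoch = 6L,
                        token_lifetime_mean = 1.25,
                        iti_constant = 0.5,
                        iti_variable_mean = 1.25,
                        threat_levels = c(0.1, 0.2, 0.3),
                        catch_window = 0.1,
                        activation_bin = 0.02,
                        approach_window = c(0.150, 2.000),
                        return_window = c(0, 2.000)) {
  stopifnot(n_epochs >= 1, tokens_per_epoch >= 1,
            token_lifetime_mean > 0, iti_constant > 0,
            iti_variable_mean > 0, catch_window > 0, activation_bin > 0,
            length(approach_window) == 2L, diff(approach_window) > 0,
            length(return_window) == 2L, diff(return_window) > 0)
  if (any(threat_levels <= 0) || any(threat_levels >= 1))
    stop("threat levels must be catch probabilities strictly in (0, 1)")
  if (is.unsorted(threat_levels, strictly = TRUE))
    stop("threat levels must be sorted in ascending order")
  obj <- list(n_epochs = as.integer(n_epochs),
              tokens_per_epoch = as.integer(tokens_per_epoch),
              token_lifetime_mean = token_lifetime_mean,
              iti_constant = iti_constant,
              iti_variable_mean = iti_variable_mean,
              threat_levels = threat_levels,
              catch_window = catch_window,
              activation_bin = activation_bin,
              approach_window = approach_window,
              return_window = return_window)
  obj$lambda1 <- 1 / token_lifetime_mean
  obj$lambda2 <- rate_from_catch_probability(threat_levels, catch_window)
  class(obj) <- "task_config"
  obj
}

#' @export
print.task_config <- function(x, ...) {
  cat("operant conflict game configuration\n")
  cat(sprintf("  %d epochs x %d tokens, token lifetime ~ Exp(mean %.3g s)\n",
              x$n_epochs, x$tokens_per_epoch, x$token_lifetime_mean))
  cat(sprintf("  ITI = carryover + %.3g s + Exp(mean %.3g s)\n",
              x$iti_constant, x$iti_variable_mean))
  cat(sprintf("  threat levels (catch prob per %.0f ms): %s\n",
              1000 * x$catch_window,
              paste(x$threat_levels, collapse = ", ")))
  cat(sprintf("  activation rates lambda2: %s /s; bin %.0f ms\n",
              paste(sprintf("%.4f", x$lambda2), collapse = ", "),
              1000 * x$activation_bin))
  invisible(x)
}
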