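# n_bins independent Bernoulli activation bins covering `duration`
exposure_bins <- function(duration, bin) ceiling(duration / bin - 1e-9)

#' Simulate predator exposures
#'
#' Draws `n` independent exposures of `duration` seconds at one threat
#' level, using the simulator's discrete activation rule: the exposure is
#' covered by 20 ms bins (from `config$activation_bin`) and the predator
#' activates independently in each bin with probability
#' `1 - exp(-lambda2 * bin)`, so that a 100 ms exposure reproduces the
#' design catch probability exactly in expectation. Uses the ambient RNG.
#'
#' @param config A [task_config()].
#' @param threat_level_index Threat level (1-based).
#' @param duration Exposure duration in seconds (default the design's
#'   reference window).
#' @param n Number of independent exposures.
#' @return Logical vector of length `n`: caught or not.
#' @examples
#' set.seed(1)
#' mean(simulate_exposures(task_config(), 1, n = 1e4))  # ~0.1
#' @export
simulate_exposures <- function(config, threat_level_index,
                               duration = config$catch_window, n = 1L) {
  stopifnot(inherits(config, "task_config"), duration >= 0, n >= 1)
  lambda2 <- config$lambda2[threat_level_index]
  nb <- exposure_bins(duration, config$activation_bin)
  if (nb == 0L) return(rep(FALSE, n))
  p_bin <- 1 - exp(-lambda2 * config$activation_bin)
  m <- matrix(stats::runif(n * nb) < p_bin, nrow = n)
  rowSums(m) > 0L
}

#' Simulate one epoch of the conflict game
#'
#' Runs up to `tokens_per_epoch` sequential token opportunities under a
#' fixed threat level. Each token's lifetime is exponential; at each
#' opportunity the agent decides whether to go and, if so, realises its
#' planned approach latency (plus truncated Gaussian noise) and exposure
#' duration. While the agent is exposed, predator activation is drawn
#' independently per `activation_bin` with probability
#' `1 - exp(-lambda2 * bin)`; the first activation catches the agent,
#' removes all tokens in hand and truncates the epoch. A token is collected
#' iff the agent goes, arrives before the token's lifetime expires, moves in
#' the correct direction, and is not caught.
#'
#' Uses the ambient RNG stream; seed upstream (see
#' [simulate_experiment()]).
#'
#' @param config A [task_config()].
#' @param policy An [aac_agent()].
#' @param threat_level_index Threat level (1-based index into
#'   `config$threat_levels`).
#' @param subject_id,epoch_id Identifiers copied into the records.
#' @return A data.frame of trial records, one row per token opportunity up
#'   to and including any catch.
#' @export
simulate_epoch <- function(config, policy, threat_level_index,
                           subject_id = 1L, epoch_id = 1L) {
  stopifnot(inherits(config, "task_config"), inherits(policy, "aac_agent"),
            threat_level_index >= 1,
            threat_level_index <= length(config$threat_levels))
  lambda2 <- config$lambda2[threat_level_index]
  p_bin <- 1 - exp(-lambda2 * config$activation_bin)
  n_tok <- config$tokens_per_epoch

  token_index <- integer(n_tok)
  potential_loss <- integer(n_tok)
  token_onset <- numeric(n_tok)
  went <- logical(n_tok)
  approach <- rep(NA_real_, n_tok)
  return_lat <- rep(NA_real_, n_tok)
  correct <- rep(NA, n_tok)
  collected <- logical(n_tok)
  caught <- logical(n_tok)

  tokens_in_hand <- 0L
  clock <- 0
  n_rec <- 0L
  for (k in seq_len(n_tok)) {
    lifetime <- stats::rexp(1, rate = 1 / config$token_lifetime_mean)
    n_rec <- k
    token_index[k] <- k
    potential_loss[k] <- tokens_in_hand
    token_onset[k] <- clock
    go <- isTRUE(policy$decide(threat_level_index, tokens_in_hand))
    went[k] <- go
    carryover <- 0
    occupied <- lifetime
    if (go) {
      t1 <- policy$plan_latency(threat_level_index, tokens_in_hand)
      if (policy$latency_noise_sd > 0)
        t1 <- t1 + stats::rnorm(1, 0, policy$latency_noise_sd)
      t1 <- max(t1, 0)
      dt <- policy$plan_return(threat_level_index, tokens_in_hand)
      if (policy$latency_noise_sd > 0)
        dt <- dt + stats::rnorm(1, 0, policy$latency_noise_sd)
      dt <- max(dt, 0.02)   # exposure stays positive: one activation bin
      approach[k] <- t1
      return_lat[k] <- dt
      correct[k] <- stats::runif(1) >= policy$error_rate

      n_bins <- exposure_bins(dt, config$activation_bin)
      caught[k] <- n_bins > 0 && any(stats::runif(n_bins) < p_bin)
      if (caught[k]) break
      collected[k] <- correct[k] && t1 < lifetime
      if (collected[k]) {
        tokens_in_hand <- tokens_in_hand + 1L
        carryover <- lifetime - t1
        occupied <- t1 + dt
      }
    }
    clock <- clock + occupied + carryover + config$iti_constant +
      stats::rexp(1, rate = 1 / config$iti_variable_mean)
  }

  idx <- seq_len(n_rec)
  data.frame(subject_id = subject_id, epoch_id = epoch_id,
             token_index = token_index[idx],
             threat_level_index = threat_level_index,
             potential_loss = potential_loss[idx],
             token_onset = token_onset[idx],
             went = went[idx],
             approach_latency = approach[idx],
             return_latency = return_lat[idx],
             correct_direction = correct[idx],
             token_collected = collected[idx],
             caught = caught[idx])
}

# deterministic per-subject sub-seed below 2^31
subject_seed <- function(seed, subject) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(subject)) %% 2147483647
}

#' Simulate a full experiment
#'
#' Runs `n_subjects` independent agents through `config$n_epochs` epochs
#' each. Epochs are assigned to threat levels in balanced randomised order
#' per subject. Each subject has a reproducible sub-seed derived from
#' `seed`, so the table for subject k does not change when `n_subjects`
#' grows.
#'
#' @param config A [task_config()].
#' @param policy An [aac_agent()].
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed governing all randomness.
#' @return A flat data.frame of trial records (see [simulate_epoch()]).
#' @examples
#' cfg <- task_config(n_epochs = 9)
#' sim <- simulate_experiment(cfg, make_fixed_agent(), n_subjects = 2,
#'                            seed = 1)
#' head(sim)
#' @export
simulate_experiment <- function(config, policy, n_subjects = 20L, seed = 1L) {
  stopifnot(inherits(config, "task_config"), inherits(policy, "aac_agent"),
            n_subjects >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  n_levels <- length(config$threat_levels)
  per_subject <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(subject_seed(seed, s))
    # balanced randomised assignment of epochs to threat levels
    levels_seq <- rep_len(seq_len(n_levels), config$n_epochs)
    levels_seq <- sample(levels_seq)
    eps <- vector("list", config$n_epochs)
    for (e in seq_len(config$n_epochs)) {
      eps[[e]] <- simulate_epoch(config, policy, levels_seq[e],
                                 subject_id = s, epoch_id = e)
    }
    per_subject[[s]] <- do.call(rbind, eps)
  }
  out <- do.call(rbind, per_subject)
  rownames(out) <- NULL
  out
}
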