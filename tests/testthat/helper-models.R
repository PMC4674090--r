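# shared fixtures: random decision models, a brute-force maximiser oracle,
# and small hand-built trial tables

# independent oracle: plain argmax of expected utility on a dense grid,
# no derivative information, no refinement
grid_argmax <- function(model, interval = c(0, 5), resolution = 0.001) {
  tt <- seq(interval[1], interval[2], by = resolution)
  z <- expected_utility(tt, model)
  tt[which.max(z)]
}

random_scenario1_model <- function() {
  bdt_model(G = runif(1, 0.5, 3),
            L = -runif(1, 0.5, 5),
            gain = gain_prior(runif(1, 0.3, 2)),
            threat = threat_scenario1(runif(1, 0.5, 4)),
            exposure = runif(1, 0.05, 0.3))
}

# scenario-2 model built from a random clamped-quadratic prior; parameters
# are drawn so that threat initially dominates the gain decay (assumption 9)
random_scenario2_model <- function() {
  repeat {
    d0 <- -runif(1, 0.8, 1.6)
    root <- runif(1, 0.8, min(1.6, 1.8 / abs(d0)))   # keep value(0) <= 1
    prior <- quadratic_threat_prior(d0, -d0 / root,
                                    anchor_t = root, anchor_p = 0.05)
    L <- -runif(1, 1, 4)
    lambda1 <- runif(1, 0.5, 1.2)
    m <- bdt_model(G = 1, L = L, gain = gain_prior(lambda1), threat = prior)
    a <- verify_assumptions(m, interval = c(0.02, root * 0.98))
    if (a$a7 && a$a8 && a$a9) return(m)
  }
}

# one hand-built epoch worth of trial records
make_epoch_records <- function(subject_id = 1L, epoch_id = 1L,
                               threat = 1L,
                               went = rep(TRUE, 6),
                               collected = went,
                               caught_at = NA,
                               approach = 0.5, return_lat = 0.2) {
  n <- if (is.na(caught_at)) length(went) else caught_at
  pot <- cumsum(c(0L, as.integer(collected)))[seq_len(n)]
  caught <- rep(FALSE, n)
  if (!is.na(caught_at)) {
    caught[n] <- TRUE
    collected[n] <- FALSE
  }
  data.frame(subject_id = subject_id, epoch_id = epoch_id,
             token_index = seq_len(n),
             threat_level_index = threat,
             potential_loss = pot,
             token_onset = cumsum(rep(2, n)) - 2,
             went = went[seq_len(n)],
             approach_latency = ifelse(went[seq_len(n)], approach, NA),
             return_latency = ifelse(went[seq_len(n)], return_lat, NA),
             correct_direction = ifelse(went[seq_len(n)], TRUE, NA),
             token_collected = collected[seq_len(n)] & !caught,
             caught = caught)
}

# cache expensive simulations across tests within a file
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (!exists(key, envir = sim_cache)) assign(key, force(expr), sim_cache)
  get(key, envir = sim_cache)
}
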