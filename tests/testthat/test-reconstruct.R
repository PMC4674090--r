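test_that("ideal-observer potential loss has the right branches and limits", {
  pars <- ideal_observer_params(D = c(4, 4, 4), P_C = c(0.1, 0.2, 0.3),
                                P_T = 0.5)
  # continuity at the branch point T = D
  expect_equal(potential_loss(1, 4, pars), -4)
  expect_equal(potential_loss(3, 4, pars), -4)
  # beyond the desired count only the held tokens are at stake
  expect_equal(potential_loss(2, 5, pars), -5)
  # no-risk limit: full expectation regardless of progress
  pars0 <- ideal_observer_params(D = c(4, 4), P_C = c(1e-9, 1e-9), P_T = 0.5)
  expect_equal(potential_loss(1, 0, pars0), -4, tolerance = 1e-6)
  expect_equal(potential_loss(1, 3, pars0), -4, tolerance = 1e-6)
  # |loss| non-decreasing in tokens in hand
  for (i in 1:3) {
    L <- potential_loss(i, 0:6, pars)
    expect_true(all(diff(abs(L)) >= -1e-12))
  }
  # alternative exponent rendering is exposed and differs
  expect_false(isTRUE(all.equal(
    potential_loss(1, 1, pars, exponent_mode = "count"),
    potential_loss(1, 1, pars))))
  expect_error(potential_loss(1, -1, pars), "non-negative")
})

test_that("level scales satisfy their defining identity", {
  pars <- ideal_observer_params(D = c(3, 3, 3), P_C = c(0.1, 0.2, 0.3),
                                P_T = 0.6)
  expect_equal(sum(1 / pars$scale_c) * mean(pars$P_C), sum(pars$P_C))
  expect_equal(pars$scale_c * pars$P_C, rep(mean(pars$P_C), 3))
})

test_that("ideal-observer estimation handles degenerate and simulated data", {
  # agent that always collects exactly 4 and is never caught
  eps <- do.call(rbind, lapply(1:5, function(e)
    make_epoch_records(epoch_id = e,
                       went = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))))
  est <- estimate_ideal_observer(eps)
  expect_equal(est$D[1], 4)
  expect_lt(est$P_C[1], 1e-6)
  expect_equal(est$P_T, 1 - 1e-12)
  # simulated always-go agent: per-level catch rate recovers the design
  sim <- cached_sim("calib_recon", simulate_experiment(
    task_config(n_epochs = 600L),
    make_fixed_agent(latency = 0.3, exposure = 0.1, noise_sd = 0),
    1, seed = 13))
  est2 <- estimate_ideal_observer(sim)
  for (i in 1:3) {
    p <- c(0.1, 0.2, 0.3)[i]
    n_go <- sum(sim$went & sim$threat_level_index == i)
    expect_lt(abs(est2$P_C[i] - p), 3 * sqrt(p * (1 - p) / n_go))
  }
  # a level with no go movements cannot be priced
  nogo <- sim
  nogo$went[nogo$threat_level_index == 2] <- FALSE
  nogo$approach_latency[nogo$threat_level_index == 2] <- NA
  nogo$caught[nogo$threat_level_index == 2] <- FALSE
  nogo$token_collected[nogo$threat_level_index == 2] <- FALSE
  expect_error(estimate_ideal_observer(nogo), "no go movements")
})

test_that("derivative points carry the right sign and scale linearly in G", {
  cond <- data.frame(threat_level_index = rep(1:3, each = 2),
                     potential_loss = rep(0:1, 3),
                     mean_approach_latency = c(0.4, 0.5, 0.45, 0.6,
                                               0.5, 0.7),
                     n_obs = 50)
  pars <- example_observer_params()
  pts <- prior_derivative_points(cond, pars)
  expect_true(all(pts$deriv <= 0))
  pts2 <- prior_derivative_points(cond, pars, G = 2)
  expect_equal(pts2$deriv, 2 * pts$deriv)
})

test_that("fitting interpolates exact lines and honours the anchor", {
  tt <- c(0.3, 0.5, 0.8, 1.0)
  pts <- data.frame(t1 = tt, deriv = -1.2 + 0.9 * tt)
  pr <- fit_prior(pts, anchor = c(0.6, 0.3))
  expect_equal(unname(pr$pars["a0"]), -1.2, tolerance = 1e-9)
  expect_equal(unname(pr$pars["a1"]), 0.9, tolerance = 1e-9)
  expect_equal(pr$value(0.6), 0.3)                  # anchoring identity
  # positive fitted line over the whole range is a constraint violation
  bad <- data.frame(t1 = tt, deriv = 0.5 + 0.1 * tt)
  expect_error(fit_prior(bad, anchor = c(0.6, 0.3)), "positive")
})

test_that("predicted latencies inherit the comparative statics", {
  pred <- predict_latencies(example_threat_prior(),
                            example_observer_params())
  for (i in 1:3) {
    pi <- pred$t1_pred[pred$threat_level_index == i]
    expect_true(all(diff(pi) >= -1e-9))   # non-decreasing in loss
  }
  # non-decreasing in threat level at fixed loss: the loss-probability
  # scaling statics, visible when the per-level losses themselves do not
  # shrink with threat (mild catch discount)
  mild <- ideal_observer_params(D = c(2, 2, 2), P_C = c(0.1, 0.2, 0.3),
                                P_T = 0.9)
  pred2 <- predict_latencies(example_threat_prior(), mild)
  for (T in 0:4) {
    pT <- pred2[pred2$potential_loss == T, ]
    pT <- pT[order(pT$threat_level_index), ]
    expect_true(all(diff(pT$t1_pred) >= -1e-9))
  }
})

test_that("the forward-inverse round trip recovers prior and latencies", {
  prior <- example_threat_prior()
  agent <- example_bdt_agent(noise_sd = 0, always_go = TRUE)
  sim <- cached_sim("roundtrip", simulate_experiment(
    task_config(), agent, n_subjects = 6, seed = 7))
  fit <- reconstruct_prior(sim)
  ok <- fit$latency$included & is.finite(fit$latency$mean_approach_latency)
  expect_gte(sum(ok), 10)
  rms <- sqrt(mean((fit$latency$t1_pred[ok] -
                      fit$latency$mean_approach_latency[ok])^2))
  expect_lt(rms, 0.05)
  # prior recovered on the observed latency range
  rng <- range(fit$points$t1[fit$points$included])
  tt <- seq(rng[1], rng[2], length.out = 100)
  expect_lt(max(abs(fit$prior$value(tt) - prior$value(tt))), 0.05)
  # an interior maximiser exists for every condition used in the fit
  expect_true(all(fit$latency$interior[ok]))
  # accessors
  expect_named(coef(fit), c("a0", "a1", "p0"))
  expect_equal(predict(fit, type = "prior", t1 = fit$anchor[1])$prior,
               fit$anchor[2], tolerance = 1e-9)
})
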