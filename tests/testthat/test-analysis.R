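test_that("implicit choices follow the stop-count rule", {
  # three collections then stop -> 1,1,1,0,0,0
  ep <- make_epoch_records(went = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ch <- reconstruct_choices(ep)
  expect_equal(nrow(ch), 6)
  expect_equal(ch$chose_at_least, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # caught epochs contribute nothing
  caught <- make_epoch_records(epoch_id = 2L, caught_at = 3)
  expect_null(reconstruct_choices(caught))
  both <- rbind(ep, caught)
  expect_equal(nrow(reconstruct_choices(both)), 6)
  # malformed epochs are rejected
  bad <- ep; bad$token_index[3] <- 5L
  expect_error(reconstruct_choices(bad), "contiguous")
})

test_that("a full no-catch session yields the maximal choice count", {
  cfg <- task_config(n_epochs = 270L)
  sim <- simulate_experiment(cfg, make_never_agent(), 1, seed = 3)
  ch <- reconstruct_choices(sim)
  expect_equal(nrow(ch), 1620)
  expect_true(all(!ch$chose_at_least))
})

test_that("choice tables are 6 x non-caught epochs with monotone records", {
  sim <- cached_sim("fixed_mid", simulate_experiment(
    task_config(n_epochs = 60L),
    make_fixed_agent(latency = 0.5, exposure = 0.3), 3, seed = 9))
  ch <- reconstruct_choices(sim)
  caught_ep <- unique(paste(sim$subject_id, sim$epoch_id)[sim$caught])
  n_total <- length(unique(paste(sim$subject_id, sim$epoch_id)))
  expect_equal(nrow(ch), 6 * (n_total - length(caught_ep)))
  for (ep in split(ch$chose_at_least, paste(ch$subject_id, ch$epoch_id)))
    expect_true(all(diff(ep) <= 0))
})

test_that("latency filters enforce the response windows and are idempotent", {
  ep <- make_epoch_records(approach = 0.576, return_lat = 0.3)
  ep$approach_latency[1] <- 0.149   # just below the window
  ep$approach_latency[2] <- 2.001
  ep$return_latency[4] <- 2.5
  f <- filter_latencies(ep)
  expect_false(1 %in% f$token_index)
  expect_false(2 %in% f$token_index)
  expect_false(4 %in% f$token_index)
  expect_true(3 %in% f$token_index)      # interior point retained
  expect_false(6 %in% f$token_index)     # 6th token dropped by design
  excl <- attr(f, "exclusions")
  expect_equal(excl$n_excluded[excl$filter == "approach_window"], 2)
  # idempotence (the kept rows are a fixed point; the second report is empty)
  f2 <- filter_latencies(f)
  expect_equal(f2, f, ignore_attr = "exclusions")
  excl2 <- attr(f2, "exclusions")
  expect_equal(excl2$n_excluded[excl2$filter == "total"], 0)
})

test_that("window exclusions are rare for the demo agent with default noise", {
  sim <- cached_sim("simple_realism", simulate_experiment(
    task_config(n_epochs = 90L), simple_bdt_agent(), 4, seed = 17))
  excl <- attr(filter_latencies(sim), "exclusions")
  window_pct <- sum(excl$pct_of_go[excl$filter %in%
                                     c("approach_window", "return_window")])
  expect_lt(window_pct, 5)
})

test_that("condition means weight subjects, not trials", {
  # degenerate balance: identical subjects -> cell mean is the subject mean
  a <- make_epoch_records(subject_id = 1L, approach = 0.6)
  b <- make_epoch_records(subject_id = 2L, approach = 0.6)
  cm <- condition_means(filter_latencies(rbind(a, b)))
  expect_equal(unique(stats::na.omit(cm$mean_approach_latency)), 0.6)
  # one subject with many extreme trials cannot dominate the cell
  slow <- do.call(rbind, lapply(1:10, function(e)
    make_epoch_records(subject_id = 2L, epoch_id = e, approach = 1.9)))
  fast <- make_epoch_records(subject_id = 1L, epoch_id = 1L, approach = 0.3)
  cm2 <- condition_means(filter_latencies(rbind(fast, slow)))
  cell <- cm2[cm2$potential_loss == 0 & cm2$threat_level_index == 1, ]
  expect_equal(cell$mean_approach_latency, (0.3 + 1.9) / 2)  # not the pooled 1.75
  # empty cells flagged, not imputed
  sparse <- make_epoch_records(went = c(TRUE, TRUE, FALSE, FALSE,
                                        FALSE, FALSE))
  cm3 <- condition_means(filter_latencies(sparse))
  empty <- cm3[cm3$potential_loss >= 2, ]
  expect_true(all(empty$n_obs == 0))
  expect_true(all(is.na(empty$mean_approach_latency)))
})

# direct construction of latency data with programmed effects
programmed_latencies <- function(n_subjects = 20, n_per_cell = 12,
                                 b_threat = 0.03, b_loss = 0.02,
                                 sd_subject = 0.05, sd_noise = 0.08,
                                 seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject_id = seq_len(n_subjects),
                      threat_level_index = 1:3, potential_loss = 0:4,
                      rep = seq_len(n_per_cell))
  b_s <- rnorm(n_subjects, 0, sd_subject)
  y <- 0.4 + b_threat * grid$threat_level_index +
    b_loss * grid$potential_loss + b_s[grid$subject_id] +
    rnorm(nrow(grid), 0, sd_noise)
  data.frame(subject_id = grid$subject_id, epoch_id = grid$rep,
             token_index = 1L,
             threat_level_index = grid$threat_level_index,
             potential_loss = grid$potential_loss,
             went = TRUE, approach_latency = y, return_latency = y / 2,
             correct_direction = TRUE, token_collected = TRUE,
             caught = FALSE)
}

test_that("trend test recovers programmed slopes and agrees with lme4", {
  d <- programmed_latencies(seed = 42)
  tr <- trend_test(d, "approach")
  expect_true(tr$converged)
  expect_lt(abs(tr$slope_threat - 0.03), 2 * tr$se["threat"])
  expect_lt(abs(tr$slope_loss - 0.02), 2 * tr$se["loss"])
  expect_lt(tr$p["threat"], 0.05)
  expect_lt(tr$p["loss"], 0.05)
  expect_equal(tr$df[2], tr$n - (4 + tr$n_subjects))
  # independent cross-check: lme4 maximum-likelihood fit, same centring
  skip_if_not_installed("lme4")
  d$thr_c <- d$threat_level_index - mean(d$threat_level_index)
  d$loss_c <- d$potential_loss - mean(d$potential_loss)
  ref <- lme4::lmer(approach_latency ~ thr_c * loss_c + (1 | subject_id),
                    data = d, REML = FALSE)
  fe <- lme4::fixef(ref)
  expect_equal(unname(tr$coefficients), unname(fe), tolerance = 1e-4)
  expect_equal(tr$sigma, stats::sigma(ref), tolerance = 1e-3)
})

test_that("trend test keeps its nominal size under the null", {
  hits <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    d <- programmed_latencies(n_subjects = 8, n_per_cell = 3,
                              b_threat = 0, b_loss = 0, seed = 1000 + r)
    tr <- trend_test(d, "approach")
    if (tr$p["threat"] < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-12)
})

test_that("permuting threat labels within subject destroys the threat effect", {
  d <- programmed_latencies(seed = 9)
  set.seed(99)
  hits <- 0L
  for (r in 1:40) {
    dp <- d
    for (s in unique(dp$subject_id)) {
      idx <- which(dp$subject_id == s)
      dp$threat_level_index[idx] <- sample(dp$threat_level_index[idx])
    }
    if (trend_test(dp, "approach")$p["threat"] < 0.05) hits <- hits + 1L
  }
  expect_lt(hits / 40, 0.2)
})

test_that("go rates are proportions that can only shrink along the token sequence", {
  sim <- cached_sim("fixed_mid", simulate_experiment(
    task_config(n_epochs = 60L),
    make_fixed_agent(latency = 0.5, exposure = 0.3), 3, seed = 9))
  gr <- go_rate_table(reconstruct_choices(sim))
  for (i in unique(gr$threat_level_index)) {
    ri <- gr$go_rate[gr$threat_level_index == i]
    expect_true(all(diff(ri) <= 1e-12))
  }
  # never-go agent: all proportions zero
  sim0 <- simulate_experiment(task_config(n_epochs = 6L),
                              make_never_agent(), 1, seed = 1)
  gr0 <- go_rate_table(reconstruct_choices(sim0))
  expect_true(all(gr0$go_rate == 0))
  # the demo agent nearly always approaches an unguarded first token
  sim1 <- cached_sim("simple_realism", simulate_experiment(
    task_config(n_epochs = 90L), simple_bdt_agent(), 4, seed = 17))
  gr1 <- go_rate_table(reconstruct_choices(sim1))
  expect_gt(min(gr1$go_rate[gr1$token_slot == 1]), 0.95)
})
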