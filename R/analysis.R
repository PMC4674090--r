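trial_columns <- c("subject_id", "epoch_id", "token_index",
                   "threat_level_index", "potential_loss", "went",
                   "approach_latency", "return_latency",
                   "correct_direction", "token_collected", "caught")

check_trial_table <- function(trials) {
  missing <- setdiff(setdiff(trial_columns, "token_onset"), names(trials))
  if (length(missing))
    stop("trial table is missing required columns: ",
         paste(missing, collapse = ", "))
  invisible(trials)
}

#' Reconstruct implicit choices from a trial table
#'
#' Because tokens are collected sequentially, a decision to stop collecting
#' implies no-go choices for all later tokens of the epoch even though no
#' explicit records exist for them. This reconstruction emits, for every
#' epoch in which the player was not caught, one record per token slot
#' (1..`tokens_per_epoch`): slot `s` is `TRUE` iff the player chose to go
#' for at least `s` tokens in that epoch. On epochs where the player was
#' caught, the intended number of collections cannot be reconstructed, so
#' those epochs contribute no records. The resulting choice set is balanced
#' with respect to potential loss but remains unbalanced over threat level
#' (more epochs are lost to catches at higher threat).
#'
#' @param trials Trial table as produced by [simulate_experiment()].
#' @return A data.frame with columns `subject_id`, `epoch_id`,
#'   `token_slot`, `threat_level_index`, `chose_at_least`.
#' @export
reconstruct_choices <- function(trials) {
  check_trial_table(trials)
  key <- interaction(trials$subject_id, trials$epoch_id, drop = TRUE)
  out <- lapply(split(trials, key), function(ep) {
    ti <- sort(ep$token_index)
    if (!identical(ti, seq_along(ti)))
      stop("malformed epoch: token indices are not contiguous from 1")
    if (any(ep$caught)) return(NULL)
    n_slots <- nrow(ep)   # non-caught epochs carry one record per token
    n_go <- sum(ep$went)
    data.frame(subject_id = ep$subject_id[1], epoch_id = ep$epoch_id[1],
               token_slot = seq_len(n_slots),
               threat_level_index = ep$threat_level_index[1],
               chose_at_least = seq_len(n_slots) <= n_go)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter approach and return latencies for analysis
#'
#' Keeps go trials whose approach latency lies inside the open approach
#' window (default 150-2000 ms) and whose return latency lies in the
#' return window (default 0-2000 ms, lower bound exclusive), and drops the
#' last token slot (the 6th token is rarely attempted, leaving design cells
#' too sparse to estimate). Go trials on epochs that later ended in a catch
#' are retained by default (`include_caught = FALSE` drops the catch trials
#' themselves and any trial of a caught epoch).
#'
#' @param trials Trial table.
#' @param approach_window,return_window Analysis windows in seconds.
#' @param drop_slot Token slot excluded from latency analyses (default 6;
#'   `NA` to keep all slots).
#' @param include_caught Keep go trials from caught epochs (default TRUE).
#' @return The filtered go-trial table; attribute `"exclusions"` holds a
#'   data.frame with per-filter counts and percentages of go trials.
#' @export
filter_latencies <- function(trials,
                             approach_window = c(0.150, 2.000),
                             return_window = c(0, 2.000),
                             drop_slot = 6L,
                             include_caught = TRUE) {
  check_trial_table(trials)
  go <- trials[trials$went %in% TRUE, , drop = FALSE]
  n_go <- nrow(go)
  bad_approach <- !(go$approach_latency > approach_window[1] &
                      go$approach_latency < approach_window[2])
  bad_return <- !(go$return_latency > return_window[1] &
                    go$return_latency <= return_window[2])
  bad_slot <- if (is.na(drop_slot)) rep(FALSE, n_go) else
    go$token_index == drop_slot
  bad_caught <- if (include_caught) rep(FALSE, n_go) else {
    caught_ep <- unique(paste(trials$subject_id, trials$epoch_id)[trials$caught])
    paste(go$subject_id, go$epoch_id) %in% caught_ep
  }
  bad_approach[is.na(bad_approach)] <- TRUE
  bad_return[is.na(bad_return)] <- TRUE
  keep <- !(bad_approach | bad_return | bad_slot | bad_caught)
  out <- go[keep, , drop = FALSE]
  rownames(out) <- NULL
  pct <- function(x) if (n_go) 100 * sum(x) / n_go else 0
  attr(out, "exclusions") <- data.frame(
    filter = c("approach_window", "return_window", "token_slot",
               "caught_epoch", "total"),
    n_excluded = c(sum(bad_approach), sum(bad_return), sum(bad_slot),
                   sum(bad_caught), sum(!keep)),
    pct_of_go = c(pct(bad_approach), pct(bad_return), pct(bad_slot),
                  pct(bad_caught), pct(!keep)))
  out
}

#' Per-condition latency estimates
#'
#' Computes mean approach and return latencies per (threat level x
#' potential loss) cell with a two-stage average: first within each
#' subject's cell, then across the subjects contributing to that cell. This
#' corrects for unbalanced designs — a subject with many trials in a cell
#' carries the same weight as one with few — unlike a pooled mean. Cells
#' without any observation are flagged missing (`n_obs = 0`, `NA` means),
#' never imputed.
#'
#' @param filtered A filtered go-trial table (see [filter_latencies()]).
#' @param max_loss Largest potential-loss level retained (default 4, since
#'   approaches after 5 collected tokens are too rare to estimate).
#' @return A data.frame with one row per condition cell: `n_obs`,
#'   `n_subjects`, `mean_approach_latency`, `mean_return_latency`.
#' @export
condition_means <- function(filtered, max_loss = 4L) {
  check_trial_table(filtered)
  d <- filtered[filtered$potential_loss <= max_loss, , drop = FALSE]
  levels_i <- sort(unique(filtered$threat_level_index))
  if (nrow(d) == 0L) {
    grid <- expand.grid(threat_level_index = levels_i,
                        potential_loss = 0:max_loss)
    grid$mean_approach_latency <- rep(NA_real_, nrow(grid))
    grid$mean_return_latency <- rep(NA_real_, nrow(grid))
    grid$n_obs <- rep(0L, nrow(grid))
    grid$n_subjects <- rep(0L, nrow(grid))
    return(grid)
  }
  grid <- expand.grid(threat_level_index = levels_i,
                      potential_loss = 0:max_loss)
  per_subj <- stats::aggregate(
    cbind(approach_latency, return_latency) ~
      subject_id + threat_level_index + potential_loss,
    data = d, FUN = mean)
  counts <- stats::aggregate(
    went ~ threat_level_index + potential_loss, data = d, FUN = length)
  across <- stats::aggregate(
    cbind(approach_latency, return_latency) ~
      threat_level_index + potential_loss,
    data = per_subj, FUN = mean)
  n_subj <- stats::aggregate(
    subject_id ~ threat_level_index + potential_loss,
    data = per_subj, FUN = function(s) length(unique(s)))
  out <- merge(grid, across, all.x = TRUE)
  out <- merge(out, stats::setNames(counts, c("threat_level_index",
                                              "potential_loss", "n_obs")),
               all.x = TRUE)
  out <- merge(out, stats::setNames(n_subj, c("threat_level_index",
                                              "potential_loss",
                                              "n_subjects")),
               all.x = TRUE)
  out$n_obs[is.na(out$n_obs)] <- 0L
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  names(out)[names(out) == "approach_latency"] <- "mean_approach_latency"
  names(out)[names(out) == "return_latency"] <- "mean_return_latency"
  out <- out[order(out$threat_level_index, out$potential_loss), ]
  rownames(out) <- NULL
  out
}

#' Linear trend test for threat level and potential loss
#'
#' Fits a random-intercept linear model to go-trial latencies with fixed
#' effects for threat level, potential loss (both entered as centred
#' numeric linear contrasts) and their interaction, plus a Gaussian random
#' subject intercept: `y ~ threat * loss + (1 | subject)`. The single
#' variance component is profiled out by a one-dimensional likelihood
#' search; if that fails the model falls back to subject-demeaned ordinary
#' least squares and flags the result. F-type statistics per effect use a
#' conservative denominator degrees of freedom `N - K`, where `K` counts
#' all modelled fixed and random effects.
#'
#' @param filtered Filtered go-trial table.
#' @param response `"approach"` or `"return"` latency.
#' @param log_latency Fit log-transformed latencies instead (the linear
#'   trend conclusions should be robust to this monotone transform).
#' @return An object of class `latency_trend` with slopes, F statistics,
#'   p-values, and variance components.
#' @export
trend_test <- function(filtered, response = c("approach", "return"),
                       log_latency = FALSE) {
  response <- match.arg(response)
  check_trial_table(filtered)
  if (length(unique(filtered$subject_id)) < 2L)
    stop("trend test needs at least two subjects")
  if (length(unique(filtered$threat_level_index)) < 2L ||
      length(unique(filtered$potential_loss)) < 2L)
    stop("trend test needs at least two levels of each factor")
  y <- if (response == "approach") filtered$approach_latency else
    filtered$return_latency
  if (log_latency) y <- log(y)
  threat <- filtered$threat_level_index - mean(filtered$threat_level_index)
  loss <- filtered$potential_loss - mean(filtered$potential_loss)
  X <- cbind("(Intercept)" = 1, threat = threat, loss = loss,
             "threat:loss" = threat * loss)
  subject <- filtered$subject_id

  fit <- fit_random_intercept(y, X, subject)
  method <- "profiled GLS (random intercept, ML)"
  if (!isTRUE(fit$converged)) {
    fit <- fit_demeaned_ols(y, X, subject)
    method <- "subject-demeaned OLS (variance profile did not converge)"
  }
  K <- ncol(X) + fit$n_groups
  df2 <- fit$n - K
  se <- sqrt(diag(fit$vcov))
  Fstat <- (fit$beta / se)^2
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(list(response = response, log_latency = log_latency,
                 coefficients = fit$beta, se = se,
                 F = Fstat, p = pval, df = c(1, df2),
                 slope_threat = unname(fit$beta["threat"]),
                 slope_loss = unname(fit$beta["loss"]),
                 sigma = fit$sigma, sigma_b = fit$sigma_b,
                 n = fit$n, n_subjects = fit$n_groups,
                 method = method,
                 converged = method == "profiled GLS (random intercept, ML)"),
            class = "latency_trend")
}

#' @export
print.latency_trend <- function(x, ...) {
  cat(sprintf("Linear trend test on %s latencies (%s)\n",
              x$response, x$method))
  cat(sprintf("  n = %d observations, %d subjects; df = (%d, %d)\n",
              x$n, x$n_subjects, x$df[1], x$df[2]))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    F = x$F, p = signif(x$p, 3))
  print(tab, digits = 4)
  cat(sprintf("  residual sd = %.4g s, subject-intercept sd = %.4g s\n",
              x$sigma, x$sigma_b))
  invisible(x)
}

#' Per-condition go proportions
#'
#' Proportion of reconstructed implicit choices that are "go" per (threat
#' level x token slot). By construction of the implicit-choice records the
#' proportion is non-increasing in token slot.
#'
#' @param choices Choice table from [reconstruct_choices()].
#' @return A data.frame with `threat_level_index`, `token_slot`, `n`,
#'   `go_rate`.
#' @export
go_rate_table <- function(choices) {
  stopifnot(all(c("threat_level_index", "token_slot", "chose_at_least")
                %in% names(choices)))
  agg <- stats::aggregate(chose_at_least ~ threat_level_index + token_slot,
                          data = choices,
                          FUN = function(v) c(n = length(v), rate = mean(v)))
  out <- data.frame(threat_level_index = agg$threat_level_index,
                    token_slot = agg$token_slot,
                    n = agg$chose_at_least[, "n"],
                    go_rate = agg$chose_at_least[, "rate"])
  out[order(out$threat_level_index, out$token_slot), ]
}
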