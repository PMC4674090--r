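#' Ideal-observer parameters
#'
#' Container for the ideal-observer quantities used to price the potential
#' loss of an approach movement: the desired token count per threat level
#' `D`, the empirical catch probability per go movement and level `P_C`,
#' the probability `P_T` of obtaining a token on an uncaught movement, and
#' the per-level scale `scale_c` (mean catch rate across levels divided by
#' the level's catch rate) that relates each level's threat prior to the
#' mean-threat baseline prior.
#'
#' @param D Numeric vector of desired token counts (> 0), one per level.
#' @param P_C Numeric vector of per-movement catch probabilities in (0, 1).
#' @param P_T Scalar probability in (0, 1).
#' @return An object of class `ideal_observer_params`.
#' @export
ideal_observer_params <- function(D, P_C, P_T) {
  stopifnot(length(D) == length(P_C), all(D > 0),
            all(P_C > 0), all(P_C < 1),
            length(P_T) == 1L, P_T > 0, P_T < 1)
  structure(list(D = D, P_C = P_C, P_T = P_T,
                 scale_c = mean(P_C) / P_C),
            class = "ideal_observer_params")
}

#' @export
print.ideal_observer_params <- function(x, ...) {
  cat("ideal-observer parameters\n")
  cat("  desired tokens D:", sprintf("%.3f", x$D), "\n")
  cat("  catch prob per movement P_C:", sprintf("%.4f", x$P_C), "\n")
  cat(sprintf("  token prob per movement P_T: %.4f\n", x$P_T))
  cat("  level scales (mean/level catch rate):",
      sprintf("%.3f", x$scale_c), "\n")
  invisible(x)
}

#' Estimate ideal-observer parameters from a trial table
#'
#' `D[i]` is the average number of tokens collected on non-caught epochs at
#' threat level i, computed per subject and then averaged across subjects.
#' `P_C[i]` is the fraction of go movements that ended in a catch at level
#' i, and `P_T` the fraction of uncaught go movements that yielded a token
#' (pooled over levels).
#'
#' @param trials Trial table.
#' @return An [ideal_observer_params()] object.
#' @export
estimate_ideal_observer <- function(trials) {
  check_trial_table(trials)
  levels_i <- sort(unique(trials$threat_level_index))
  ep_key <- paste(trials$subject_id, trials$epoch_id)
  caught_ep <- unique(ep_key[trials$caught])

  D <- P_C <- numeric(length(levels_i))
  for (j in seq_along(levels_i)) {
    li <- trials$threat_level_index == levels_i[j]
    go <- trials[li & trials$went %in% TRUE, , drop = FALSE]
    if (!nrow(go))
      stop("no go movements at threat level ", levels_i[j],
           "; ideal observer cannot be estimated")
    P_C[j] <- mean(go$caught)
    # per-subject mean tokens per non-caught epoch, then across subjects
    nc <- trials[li & !(ep_key %in% caught_ep), , drop = FALSE]
    if (!nrow(nc))
      stop("no non-caught epochs at threat level ", levels_i[j])
    per_ep <- stats::aggregate(token_collected ~ subject_id + epoch_id,
                               data = nc, FUN = sum)
    per_subj <- stats::aggregate(token_collected ~ subject_id,
                                 data = per_ep, FUN = mean)
    D[j] <- mean(per_subj$token_collected)
  }
  go_all <- trials[trials$went %in% TRUE & !trials$caught, , drop = FALSE]
  P_T <- mean(go_all$token_collected)
  eps <- 1e-12
  ideal_observer_params(D = pmax(D, eps),
                        P_C = pmin(pmax(P_C, eps), 1 - eps),
                        P_T = pmin(pmax(P_T, eps), 1 - eps))
}

#' Ideal-observer potential loss
#'
#' Expected utility at stake when moving for a token: getting caught
#' forfeits the expectation of ending the epoch with the desired `D[i]`
#' tokens. With `T` tokens already in hand, reaching `D[i]` requires about
#' `(D[i] - T) / P_T` further movements, each surviving with probability
#' `1 - P_C[i]`, so the loss is `-D[i] * (1 - P_C[i])^((D[i] - T) / P_T)`
#' while `T < D[i]`, and `-T` (the tokens actually held) once `T >= D[i]`.
#' The two branches agree at `T = D[i]`. This accounting explains approach
#' delay even at zero tokens in hand, where the naive loss would vanish.
#'
#' `exponent_mode = "count"` selects an alternative reading of the
#' discount, `-D[i] * (1 - P_C[i])^(D[i] - T) / P_T`, which discounts per
#' token rather than per attempt (and is discontinuous at the branch
#' point); the per-attempt form is the default.
#'
#' @param level Threat level index (1-based).
#' @param tokens_in_hand Tokens already collected this epoch (vectorised).
#' @param params An [ideal_observer_params()].
#' @param exponent_mode `"attempts"` (default) or `"count"`.
#' @return Non-positive utility in token units.
#' @export
potential_loss <- function(level, tokens_in_hand, params,
                           exponent_mode = c("attempts", "count")) {
  exponent_mode <- match.arg(exponent_mode)
  stopifnot(inherits(params, "ideal_observer_params"),
            level >= 1, level <= length(params$D))
  T <- tokens_in_hand
  if (any(T < 0)) stop("tokens in hand must be non-negative")
  D <- params$D[level]
  P_C <- params$P_C[level]
  below <- T < D
  out <- numeric(length(T))
  out[!below] <- -T[!below]
  if (exponent_mode == "attempts") {
    out[below] <- -D * (1 - P_C)^((D - T[below]) / params$P_T)
  } else {
    out[below] <- -D * (1 - P_C)^(D - T[below]) / params$P_T
  }
  out
}

#' Loss function for a decision-theoretic agent
#'
#' Adapts [potential_loss()] to the `(level, tokens_in_hand)` signature
#' expected by [make_bdt_agent()], so simulated agents can price movements
#' with the same opportunity-cost accounting that the reconstruction
#' assumes.
#'
#' @param params An [ideal_observer_params()].
#' @param exponent_mode Passed to [potential_loss()].
#' @return A function `(level, tokens) -> negative utility`.
#' @export
make_ideal_observer_loss <- function(params,
                                     exponent_mode = c("attempts", "count")) {
  exponent_mode <- match.arg(exponent_mode)
  function(level, tokens)
    potential_loss(level, tokens, params, exponent_mode)
}

#' Solve the stationarity condition for the prior's derivative
#'
#' At an interior optimum the derivative of expected gain balances the
#' derivative of expected loss. Given per-condition mean approach latencies,
#' the time derivative of the mean-threat baseline prior at each latency is
#' therefore `-scale_c[i] / L[i,T] * dE(G)/dt1`, with
#' `dE(G)/dt1 = -G * lambda1 * exp(-lambda1 * t1)` and `L[i,T]` the
#' ideal-observer potential loss. Conditions with zero potential loss are
#' skipped with a warning.
#'
#' @param cond Condition-mean table (see [condition_means()]); rows with
#'   missing latencies are ignored.
#' @param params An [ideal_observer_params()].
#' @param gain A [gain_prior()].
#' @param G Gain utility per token.
#' @param exponent_mode Passed to [potential_loss()].
#' @return A data.frame with one row per usable condition: the latency
#'   `t1`, the implied prior derivative `deriv`, and the loss used.
#' @export
prior_derivative_points <- function(cond, params, gain = gain_prior(0.8),
                                    G = 1,
                                    exponent_mode = c("attempts", "count")) {
  exponent_mode <- match.arg(exponent_mode)
  stopifnot(inherits(params, "ideal_observer_params"),
            inherits(gain, "gain_prior"))
  cond <- cond[is.finite(cond$mean_approach_latency), , drop = FALSE]
  if (!nrow(cond)) stop("no conditions with observed latencies")
  L <- mapply(function(i, T) potential_loss(i, T, params, exponent_mode),
              cond$threat_level_index, cond$potential_loss)
  zero <- L == 0
  if (any(zero)) {
    warning(sum(zero), " condition(s) with zero potential loss skipped")
    cond <- cond[!zero, , drop = FALSE]
    L <- L[!zero]
  }
  t1 <- cond$mean_approach_latency
  dEG <- G * gain$d1(t1)
  deriv <- -params$scale_c[cond$threat_level_index] / L * dEG
  data.frame(threat_level_index = cond$threat_level_index,
             potential_loss = cond$potential_loss,
             n_obs = cond$n_obs,
             t1 = t1, loss = L, deriv = deriv)
}

#' Fit the reconstructed threat prior
#'
#' Least-squares first-order polynomial through the derivative points,
#' clamped at zero from above (the prior may only decay, so positive parts
#' of the fitted line are set to zero and the prior is constant past the
#' clamp root). The clamped derivative is integrated analytically and the
#' integration constant anchored so that the prior equals `anchor[2]`
#' (typically the average catch rate) at `anchor[1]` (the average approach
#' latency). Values are additionally kept inside \[0, 1\].
#'
#' @param points Data.frame with columns `t1` and `deriv` (see
#'   [prior_derivative_points()]).
#' @param anchor Numeric length-2: `(latency, probability)` anchoring
#'   point.
#' @param t_max Support upper end in seconds.
#' @return An object of class `c("reconstructed_prior", "threat_prior")`
#'   with elements `pars` (`a0`, `a1`, `p0`), `anchor`, and the usual
#'   value/derivative interface.
#' @export
fit_prior <- function(points, anchor, t_max = 5) {
  stopifnot(nrow(points) >= 2L, length(anchor) == 2L,
            anchor[1] >= 0, anchor[2] >= 0, anchor[2] <= 1)
  fit <- stats::lm(deriv ~ t1, data = points)
  a0 <- unname(stats::coef(fit)[1])
  a1 <- unname(stats::coef(fit)[2])
  rng <- range(points$t1)
  if (all(a0 + a1 * seq(rng[1], rng[2], length.out = 101L) > 0))
    stop("fitted derivative is positive over the whole latency range; ",
         "a decaying threat prior cannot be reconstructed")

  # integral of the clamped derivative min(a0 + a1 t, 0) from 0 to t
  antider <- function(u) a0 * u + a1 * u^2 / 2
  int_d <- function(t) {
    if (a1 == 0) return(min(a0, 0) * t)
    r <- -a0 / a1
    if (a1 > 0) {
      # line rises: negative (if at all) before r
      lo <- pmin(t, max(r, 0))
      antider(lo)
    } else {
      # line falls: negative after r
      r0 <- max(r, 0)
      ifelse(t <= r0, 0, antider(t) - antider(r0))
    }
  }
  p0 <- anchor[2] - int_d(anchor[1])
  raw <- function(t1) p0 + int_d(t1)
  inside <- function(t1) {
    v <- raw(t1)
    v > 0 & v < 1
  }
  value <- function(t1) pmin(pmax(raw(t1), 0), 1)
  d1 <- function(t1) ifelse(inside(t1), pmin(a0 + a1 * t1, 0), 0)
  d2 <- function(t1)
    ifelse(inside(t1) & (a0 + a1 * t1) < 0, a1, 0)

  obj <- threat_prior(value, d1, d2, support = c(0, t_max), check = FALSE)
  obj$pars <- c(a0 = a0, a1 = a1, p0 = p0)
  obj$anchor <- c(t = unname(anchor[1]), p = unname(anchor[2]))
  obj$lm <- fit
  class(obj) <- c("reconstructed_prior", class(obj))
  obj
}

#' @export
print.reconstructed_prior <- function(x, ...) {
  cat("reconstructed threat prior (clamped linear derivative)\n")
  cat(sprintf("  derivative: min(%.4g %+.4g t, 0) 1/s\n",
              x$pars["a0"], x$pars["a1"]))
  cat(sprintf("  anchored at prior(%.3g s) = %.3g\n",
              x$anchor["t"], x$anchor["p"]))
  invisible(x)
}

#' Predict approach latencies from a threat prior
#'
#' Forward pass of the reconstruction: for each (threat level, potential
#' loss) condition a decision model is assembled with loss utility
#' `potential_loss(level, T)`, the baseline prior scaled by
#' `1 / scale_c[level]`, and the stated gain prior, and its optimal
#' latency computed. Conditions whose optimum sits on the search boundary
#' are flagged (`interior = FALSE`).
#'
#' @param prior A [threat_prior()] (typically a reconstructed prior).
#' @param params An [ideal_observer_params()].
#' @param conditions Data.frame with columns `threat_level_index` and
#'   `potential_loss`; defaults to the full grid of levels x loss 0..4.
#' @param gain A [gain_prior()].
#' @param G Gain utility per token.
#' @param interval,resolution Passed to [optimal_latency()].
#' @param exponent_mode Passed to [potential_loss()].
#' @return `conditions` augmented with `loss`, `t1_pred`, `utility`, and
#'   `interior`.
#' @export
predict_latencies <- function(prior, params, conditions = NULL,
                              gain = gain_prior(0.8), G = 1,
                              interval = c(0, 5), resolution = 0.001,
                              exponent_mode = c("attempts", "count")) {
  exponent_mode <- match.arg(exponent_mode)
  stopifnot(inherits(prior, "threat_prior"),
            inherits(params, "ideal_observer_params"))
  if (is.null(conditions))
    conditions <- expand.grid(threat_level_index = seq_along(params$D),
                              potential_loss = 0:4)
  n <- nrow(conditions)
  loss <- t1_pred <- util <- numeric(n)
  interior <- logical(n)
  for (r in seq_len(n)) {
    i <- conditions$threat_level_index[r]
    T <- conditions$potential_loss[r]
    loss[r] <- potential_loss(i, T, params, exponent_mode)
    thr <- scale_threat_prior(prior, 1 / params$scale_c[i])
    m <- bdt_model(G = G, L = min(loss[r], -1e-9), gain = gain,
                   threat = thr)
    opt <- optimal_latency(m, interval, resolution)
    t1_pred[r] <- opt$t1
    util[r] <- opt$utility
    interior[r] <- !opt$boundary
  }
  out <- conditions
  out$loss <- loss
  out$t1_pred <- t1_pred
  out$utility <- util
  out$interior <- interior
  out
}

#' Reconstruct the threat prior implied by observed approach latencies
#'
#' End-to-end inversion: filters the trial table, computes condition-mean
#' latencies, estimates the ideal observer, converts each included
#' condition's latency into a point on the prior's time derivative, fits
#' the constrained first-order polynomial, integrates and anchors it at the
#' average catch rate / average approach latency, and finally feeds the
#' fitted prior back through the decision model to predict per-condition
#' latencies.
#'
#' @param trials Trial table (see [simulate_experiment()] /
#'   [read_trials()]).
#' @param gain A [gain_prior()]; its rate should match the task's token
#'   lifetime.
#' @param G Gain utility per token (fixed at 1 by convention: all utilities
#'   are in token units).
#' @param min_n Minimum observations for a condition cell to enter the
#'   derivative fit.
#' @param max_loss Largest potential-loss level analysed.
#' @param t_max Support upper end / forward search window in seconds.
#' @param exponent_mode Rendering of the ideal-observer discount, see
#'   [potential_loss()].
#' @param filter_args List of extra arguments for [filter_latencies()].
#' @return An object of class `prior_fit` bundling the fitted prior
#'   (`$prior`), ideal-observer parameters (`$params`), derivative points
#'   (`$points`, with `included` flag), the predicted-vs-observed latency
#'   table (`$latency`), and the anchor.
#' @seealso [coef.prior_fit()], [predict.prior_fit()], [plot.prior_fit()]
#' @export
reconstruct_prior <- function(trials, gain = gain_prior(0.8), G = 1,
                              min_n = 10L, max_loss = 4L, t_max = 5,
                              exponent_mode = c("attempts", "count"),
                              filter_args = list()) {
  exponent_mode <- match.arg(exponent_mode)
  filtered <- do.call(filter_latencies, c(list(trials), filter_args))
  cond <- condition_means(filtered, max_loss = max_loss)
  params <- estimate_ideal_observer(trials)
  points <- prior_derivative_points(cond, params, gain, G, exponent_mode)
  points$included <- points$n_obs >= min_n
  if (sum(points$included) < 2L)
    stop("fewer than two condition cells pass the minimum observation count")
  obs <- points[points$included, , drop = FALSE]
  anchor <- c(mean(obs$t1), mean(params$P_C))
  prior <- fit_prior(obs, anchor, t_max = t_max)
  pred <- predict_latencies(prior, params,
                            conditions = cond[, c("threat_level_index",
                                                  "potential_loss")],
                            gain = gain, G = G, interval = c(0, t_max),
                            exponent_mode = exponent_mode)
  latency <- merge(cond, pred, by = c("threat_level_index",
                                      "potential_loss"))
  latency$included <- latency$n_obs >= min_n
  latency <- latency[order(latency$threat_level_index,
                           latency$potential_loss), ]
  rownames(latency) <- NULL
  structure(list(prior = prior, params = params, points = points,
                 latency = latency, anchor = anchor, gain = gain, G = G,
                 min_n = min_n, t_max = t_max,
                 exponent_mode = exponent_mode),
            class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  cat("Threat-prior reconstruction from approach latencies\n\n")
  print(x$prior)
  cat("\n")
  print(x$params)
  ok <- x$latency$included
  rmse <- sqrt(mean((x$latency$t1_pred[ok] -
                       x$latency$mean_approach_latency[ok])^2, na.rm = TRUE))
  cat(sprintf("\n  %d/%d condition cells in the fit; latency RMSE %.1f ms\n",
              sum(x$points$included), nrow(x$points), 1000 * rmse))
  cat(sprintf("  interior optimum in %d/%d predicted conditions\n",
              sum(x$latency$interior), nrow(x$latency)))
  invisible(x)
}

#' @export
summary.prior_fit <- function(object, ...) {
  print(object)
  cat("\nPredicted vs observed mean approach latencies (s):\n")
  print(object$latency[, c("threat_level_index", "potential_loss", "n_obs",
                           "mean_approach_latency", "t1_pred", "interior",
                           "included")],
        digits = 4, row.names = FALSE)
  invisible(object)
}

#' @rdname reconstruct_prior
#' @param object,x A `prior_fit`.
#' @param ... Unused.
#' @export
coef.prior_fit <- function(object, ...) object$prior$pars

#' Predict method for reconstructed priors
#'
#' With `type = "latency"` (default) returns the per-condition predicted
#' optimal approach latencies; with `type = "prior"` evaluates the fitted
#' prior at latencies `t1`.
#'
#' @param object A `prior_fit`.
#' @param type `"latency"` or `"prior"`.
#' @param conditions Optional condition grid for `type = "latency"`.
#' @param t1 Latencies at which to evaluate the prior for
#'   `type = "prior"`.
#' @param ... Unused.
#' @export
predict.prior_fit <- function(object, type = c("latency", "prior"),
                              conditions = NULL, t1 = NULL, ...) {
  type <- match.arg(type)
  if (type == "prior") {
    if (is.null(t1)) t1 <- seq(0, object$t_max, length.out = 101L)
    return(data.frame(t1 = t1, prior = object$prior$value(t1)))
  }
  if (is.null(conditions))
    return(object$latency)
  predict_latencies(object$prior, object$params, conditions,
                    gain = object$gain, G = object$G,
                    interval = c(0, object$t_max),
                    exponent_mode = object$exponent_mode)
}

#' Diagnostic plot of a prior reconstruction
#'
#' Two panels: predicted versus observed per-condition approach latencies
#' (one line per threat level), and the derivative points with the fitted
#' clamped line plus the integrated, anchored prior.
#'
#' @param x A `prior_fit`.
#' @param ... Unused.
#' @export
plot.prior_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lat <- x$latency
  cols <- c("#2166ac", "#f4a582", "#b2182b")
  graphics::plot(lat$potential_loss, lat$mean_approach_latency,
                 col = cols[lat$threat_level_index],
                 pch = ifelse(lat$included, 19, 1),
                 xlab = "potential loss (tokens)",
                 ylab = "approach latency (s)",
                 main = "observed vs predicted")
  for (i in unique(lat$threat_level_index)) {
    li <- lat[lat$threat_level_index == i, ]
    graphics::lines(li$potential_loss, li$t1_pred, col = cols[i], lwd = 2)
  }
  tt <- seq(0, x$t_max, length.out = 200L)
  graphics::plot(tt, x$prior$value(tt), type = "l", lwd = 2,
                 ylim = c(min(0, min(x$points$deriv)), 1),
                 xlab = "approach latency (s)", ylab = "probability / 1/s",
                 main = "reconstructed prior")
  graphics::lines(tt, pmin(x$prior$pars["a0"] + x$prior$pars["a1"] * tt, 0),
                  col = "grey50")
  graphics::points(x$points$t1, x$points$deriv,
                   col = ifelse(x$points$included, "red", "grey70"),
                   pch = 19, cex = 0.7)
  invisible(x)
}
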