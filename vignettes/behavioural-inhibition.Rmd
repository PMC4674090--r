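---
title: "Behavioural inhibition as a cost-minimising strategy: model, simulator, and prior reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural inhibition as a cost-minimising strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacbdt)
```

## The decision problem

In an operant conflict test an agent is rewarded for approaching a goal
(a food pellet, a game token) but risks punishment for the same movement.
Two quantities describe each approach: the **approach latency** $t_1$,
the time from reward appearance to leaving the safe position, and the
**return latency** (exposure duration) $\Delta t$, the time spent
outside it. Rewards decay: the reward lifetime is exponential with rate
$\lambda_1$, so the probability that the reward is still there on
arrival is

$$P_G(t_1) = e^{-\lambda_1 t_1}.$$

The punisher activates as a Poisson process with rate $\lambda_2$ while
the agent is exposed; under these *objective* statistics the probability
of punishment is

$$P_L(\Delta t) = 1 - e^{-\lambda_2 \Delta t},$$

independent of $t_1$. With gain utility $G > 0$ and loss utility
$L < 0$, and with no sensory information about the outcome (so both
probabilities are priors), the agent maximises expected utility

$$Z(t_1, \Delta t) = P_L \, L + P_G \, G .$$

Two belief regimes follow ("scenarios" throughout the package):

* **Scenario 1** — the prior matches the objective statistics. Since
  $\partial E(L)/\partial t_1 = 0$ (exposure duration is planned
  independently of the approach time; see assumptions below),
  $\partial Z/\partial t_1 = -G\lambda_1 e^{-\lambda_1 t_1} < 0$: the
  optimum is the earliest biologically possible latency, whatever the
  threat level or the stakes. `optimal_latency()` therefore returns the
  left end of any search interval for these models, flagged
  `boundary = TRUE`.

* **Scenario 2** — the prior encodes a temporal correlation between
  reward and threat, as when a predator is alerted by the same event
  that creates the foraging opportunity and loses interest over time:
  threat probability is high just after a reward appears and decays
  afterwards, $\partial P_L/\partial t_1 < 0$. If the expected loss
  initially decays faster than the expected gain and asymptotes sooner
  (the two derivative curves cross), $\partial Z/\partial t_1$ changes
  sign from + to −, so an interior maximiser $t_1^* > 0$ exists:
  *behavioural inhibition* — waiting before approaching — is then the
  cost-minimising strategy, not a malfunction.

`verify_assumptions()` checks the three scenario-2 conditions on a grid
(labelled a7–a9 in the code): prior decay, gain decay, and the crossing.
The crossing condition is implemented as
$\partial E(L)/\partial t_1 > -\,\partial E(G)/\partial t_1$ at the left
end of the interval and the reverse at the right end, i.e. it compares
the (positive) decay rate of the expected loss with the magnitude of the
(negative) gain derivative. Written this way it is exactly the condition
that forces the sign change of $\partial Z/\partial t_1$; comparing the
two signed derivatives directly would be vacuous, since a positive
number always exceeds a negative one.

The diagnostic signature that separates the scenarios is **comparative
statics**, obtained from first-order Taylor expansions of the
stationarity condition around $t_1^*$: inflating the loss magnitude
($L' = kL$, $k > 1$) or the loss probability ($P_L' = kP_L$) moves the
interior optimum to *later* times, whereas under scenario 1 — even with
a time-dependent motor cost added, which can also produce an interior
optimum — the optimum ignores both. `latency_shift_under_scaling()`
implements the perturbation; the motor cost is parameterised as
$c(t_1) = c_0 e^{-r t_1}$ (urgency is costly, relaxing with latency),
which suffices to create a non-trivial optimum under scenario 1 while
leaving it insensitive to loss scaling.

Modelling assumptions carried by the types: utilities are quantifiable
constants combining linearly; the gain distribution is known; motor
execution is deterministic; the go/no-go decision and the latency plan
are made before the reward appears; and $\Delta t$ is independent of
$t_1$, so only the $t_1$-dependence enters the optimisation. For
scenario-2 models the loss probability is treated as separable, with the
exposure-dependent factor absorbed into the prior's scale.

## Numerical choices

`optimal_latency()` scans a dense grid (default step 1 ms) over the
search interval and then refines by bisection on the analytic derivative
in the bracket around the best grid point, accepting the root only if it
does not lower the utility. Among equal optima the smallest latency
wins (the theory proves existence, not uniqueness). Derivatives are
analytic throughout — every prior carries `value`/`d1`/`d2` functions —
and the test suite checks them against central finite differences at
relative tolerance $10^{-6}$. Probability scaling caps $kP_L$ at 1; the
cap zeroes the derivative where it binds, and
`latency_shift_under_scaling()` refuses to scale when the cap binds
inside the searched interval, since the statics argument assumes an
unconstrained neighbourhood. Units are seconds everywhere inside the
package; milliseconds appear only in printed summaries.

The canonical scenario-2 prior is the **clamped-quadratic** family
(`quadratic_threat_prior()`): the prior's time derivative is linear,
$d(t) = \min(d_0 + a_1 t,\, 0)$ with $d_0 < 0$, integrated analytically
and anchored to pass through a stated probability at a stated latency;
past the clamp root the prior is constant. This is the same
three-parameter family the reconstruction stage fits, which is what
makes an exact forward–inverse round trip possible.

## The simulated conflict game

`task_config()` / `simulate_experiment()` emulate a virtual foraging
game. Per epoch, up to 6 reward tokens appear sequentially; token
lifetimes are exponential with mean 1.25 s; the inter-token interval is
the carried-over remaining lifetime of a collected token plus a 0.5 s
constant and an exponential part with mean 1.25 s (so neither going nor
staying buys time). A predator guards the arena at one of three threat
levels, specified as catch probabilities per 100 ms of exposure
(0.1/0.2/0.3); the implied activation rates are
$\lambda_2 = -\ln(1-p)/\Delta t$, i.e. 1.0536/s, 2.2314/s and 3.5667/s.
During exposure, activation is drawn independently in 20 ms bins with
per-bin probability $1 - e^{-\lambda_2 \cdot 0.02}$ — chosen so that
five bins compound *exactly* to the design probability, an identity the
tests assert. A catch removes all tokens in hand and truncates the
epoch. Activations while the player is safe self-deactivate, so only
exposure-time hazard is simulated (distributionally identical, simpler);
the whole out-of-safe interval counts as exposure, whether or not a
token is present. Epochs are assigned to threat levels in balanced
randomised blocks per subject, and each subject gets a deterministic
sub-seed from the master seed, so existing subjects are unchanged when
more are added.

Agent policies (`aac_agent()`) plug into the simulator: planned approach
latency and exposure per (threat level, tokens in hand) condition, plus
Gaussian latency noise (default sd 50 ms, truncated at zero) and a
condition-independent wrong-direction probability (default 0.028,
i.e. 97.2% correct). `make_bdt_agent()` builds the decision-theoretic
agent: it precomputes, per condition, the optimal latency of a
`bdt_model` whose baseline threat prior is scaled by the level's
loss-probability factor and whose loss utility comes from a configurable
`loss_fun`; it goes when the achieved expected utility is positive.

What the generator does **not** emulate: learning or trial-to-trial
updating of the prior (the model is static per decision), sequential
position effects, motor kinematics, fatigue, and any physiological
channel. Passing recovery tests on these data therefore shows that the
pipeline inverts its own generative assumptions faithfully — not that
real subjects obey them.

## Behavioural analysis

`reconstruct_choices()` expands each non-caught epoch into six implicit
go/no-go records (slot $s$ is "go" iff at least $s$ tokens were pursued
that epoch), because a decision to stop implies no-go for every later
token; caught epochs are dropped since the intended count cannot be
known. The resulting table is balanced over potential loss but not over
threat level. A complete 270-epoch session yields exactly 1620 records.
Choice data are summarised as condition proportions only
(`go_rate_table()`); they are autocorrelated across the loss factor by
construction, so no inferential statistics are attached to them.

`filter_latencies()` keeps go trials with approach latency strictly
inside 150–2000 ms and return latency in (0, 2000] ms, and drops the 6th
token slot, whose design cells are too sparse to estimate; the analysis
design is thus 3 threat levels × 5 loss levels (0–4). Go trials from
epochs that later ended in a catch are included by default
(`include_caught = FALSE` switches this off); the movements before the
catch are valid observations of the latency plan.

`condition_means()` averages within subject–condition cells first and
then across the subjects contributing to a cell, bounding any one
subject's influence by $1/n_\text{subjects}$ regardless of trial
counts; empty cells are flagged, never imputed.

`trend_test()` fits the latency model
`y ~ threat * loss + (1 | subject)` with threat level and potential loss
as centred numeric linear contrasts. The single random-intercept
variance is profiled out of the Gaussian likelihood: with
$\theta = \sigma_b^2/\sigma^2$ the block-diagonal covariance inverts in
closed form, leaving a one-dimensional profile maximised by bounded
search — a self-contained estimator for exactly this model class, which
the tests cross-check against an `lme4` maximum-likelihood fit on the
same data. If the profile search fails the function falls back to
subject-demeaned OLS and flags it. F-type statistics use the
conservative denominator degrees of freedom $N - K$, with $K$ the count
of all modelled fixed and random effects. A log-latency refit is
available via `log_latency = TRUE`. Random-slope models are out of
scope; the random-intercept specification is the primary one.

## Reconstructing the threat prior from latencies

`reconstruct_prior()` implements the inversion. An **ideal observer**
prices each movement: subjects are assumed to aim for $D_i$ tokens at
threat level $i$ (estimated as the per-subject mean tokens collected on
non-caught epochs, averaged across subjects); with $T$ tokens in hand,
catch probability $P_C$ per movement and token probability $P_T$ per
uncaught movement, getting caught forfeits

$$L_{i,T} = -D_i (1 - P_{C,i})^{(D_i - T)/P_T} \quad (T < D_i), \qquad
  L_{i,T} = -T \quad (T \ge D_i).$$

The exponent $(D_i - T)/P_T$ counts the expected number of remaining
attempts; the printed form of this expression is ambiguous between that
reading and a per-token discount with a $1/P_T$ prefactor, so the
alternative is exposed behind `exponent_mode = "count"` — the
per-attempt form is the default because it is continuous at the branch
point and reproduces the forward model in the round-trip test, which is
the verifiable criterion. The opportunity-cost accounting explains
approach delay even at zero tokens in hand.

At an interior optimum the stationarity condition can be solved for the
prior's time derivative at the observed latency:

$$\frac{\partial \bar P_L}{\partial t_1}
  = -\frac{\bar P / P_i}{L_{i,T}} \frac{\partial E(G)}{\partial t_1},$$

where $\bar P/P_i$ (`scale_c`) is the mean catch rate across levels
divided by the level's catch rate, treating each level's prior as a
scaled copy of a common mean-threat baseline. The placement of this
scale factor is the one under which prediction inverts reconstruction
exactly — again the round-trip test is the criterion. Conditions enter
the fit at loss levels 0–4 on all three levels, excluding cells below a
minimum observation count (default 10; the exclusion rule for sparse
cells is a package choice). The points are fit with a first-order
polynomial, clamped at zero from above (the prior may only decay),
integrated analytically, and anchored so the prior equals the average
catch rate at the average approach latency. Feeding the fitted prior
back through the decision model (loss from the ideal observer, prior
scaled by $1/\text{scale}_c$, forward search over $[0, 5]$ s — far
beyond any observed latency) yields predicted per-condition latencies
and flags conditions without an interior optimum. $G$ is fixed at one
token-utility; all losses are in token units, and predictions are
invariant under common rescaling of all utilities. Subject-specific
priors are out of scope.

## The calibrated examples

The package ships two reference agents whose parameters were fixed once,
by design:

* `example_bdt_agent()` — the self-consistent round-trip agent. Its
  prior `example_threat_prior()` (derivative intercept −1.35/s, slope
  1.35/s², anchored at probability 0.2 at 0.74 s) and observer
  parameters `example_observer_params()` ($D = (3.32, 3.23, 3.56)$,
  $P_C = (0.1, 0.2, 0.3)$, $P_T = 0.58$) are the fixed point of
  simulate-then-re-estimate iteration under the default task: data
  simulated from the agent return these same estimates, and the mean
  simulated latency sits at the anchoring point with the mean design
  catch rate 0.2. This self-consistency is what lets the
  forward–inverse round trip recover the prior to a few hundredths and
  the latencies to about 10 ms RMS. One honest wrinkle: at the highest
  threat level the ideal-observer loss at zero tokens in hand is so
  heavily discounted (each future attempt survives with probability
  0.7) that the optimum for that single cell collapses to zero latency;
  the cell yields no analysable latencies and is excluded from the fit,
  and the reconstruction is unaffected.

* `simple_bdt_agent()` — the comparative-statics demonstrator. Its loss
  is the tokens at stake plus a fixed two-token opportunity offset,
  identical across levels, and its prior (derivative intercept −1.2/s,
  slope 1.2/s², anchored at 0.05 at 0.8 s) is steep enough that every
  condition has an interior optimum comfortably inside the response
  window. Its latencies increase strictly with both threat level and
  potential loss, so it is the agent used to demonstrate end-to-end
  sign recovery through the full pipeline.

```{r demo, eval = FALSE}
cfg <- run_config(agent = list(type = "bdt_simple"),
                  n_subjects = 8, seed = 2024)
bundle <- run_demo(cfg, out_dir = "demo-out")
bundle$trend_approach      # positive threat and loss slopes
plot(bundle$prior_fit)
```

## Problem sizes and verification

The test suite verifies closed forms against independent oracles
(numerical integration for the survival function, brute-force 1 ms grid
maximisation for the optimiser and the comparative statics, `lme4` for
the mixed model), property-tests the derivative contracts and the
scenario dichotomy over random parameter draws, and runs the full
pipeline at deliberately moderate sizes: recovery and round-trip checks
use 4–8 simulated subjects at 90–270 epochs each, and Monte-Carlo
calibration checks use $10^4$–$10^5$ draws with 3-standard-error
tolerances. These sizes give comfortable statistical margins for every
asserted property while keeping a full run fast.

## Limitations

The estimator hierarchy is intentionally minimal: condition proportions
instead of a logistic mixed model for choices, a single profiled
variance component instead of general REML machinery, and a group-level
(not subject-level) prior reconstruction. The reconstruction assumes an
ideal observer with linear utilities and no premium on being caught;
it demonstrates that *a* plausible prior can rationalise the latencies,
not that agents used it. The example prior of the figures-style
simulations is the package's own documented choice and does not claim
to reproduce any particular published curve.
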