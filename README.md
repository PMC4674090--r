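# aacbdt

Behavioural inhibition — hesitating before approaching a reward under
threat — is the core anxiety-like readout of operant conflict tests in
rodents and humans. It is easy to read as a malfunction: under the
objective statistics of such tests (reward decays, threat hazard is
constant during exposure) the optimal policy is to move as early as
possible, whatever the stakes. `aacbdt` implements a
Bayesian-decision-theoretic account on which the delay is *normative*:
if the agent's prior encodes a temporal correlation between reward and
threat — threat probability high just after a reward appears, decaying
afterwards — then waiting minimises expected cost, and the optimal
latency grows with both the probability and the magnitude of potential
loss.

The package is aimed at computational-psychiatry and decision-science
researchers who want to simulate, analyse, and invert this model.

## The model

The agent chooses its approach latency $t_1$ to maximise

$$Z(t_1) \;=\; P_L(t_1)\,L \;+\; P_G(t_1)\,G,
\qquad P_G(t_1) = e^{-\lambda_1 t_1},$$

with gain utility $G > 0$, loss utility $L < 0$, and a prior loss
probability $P_L$. Two regimes:

* **Scenario 1** (objective statistics): $P_L$ depends only on the
  exposure duration, $P_L = 1 - e^{-\lambda_2 \Delta t}$, so
  $\partial Z/\partial t_1 < 0$ and the optimum is the earliest
  possible latency — independent of threat and stakes.
* **Scenario 2** (correlated-threat prior): $\partial P_L/\partial t_1
  < 0$ with expected loss initially decaying faster than expected gain;
  then $\partial Z/\partial t_1$ crosses zero from above and an
  interior optimum $t_1^* > 0$ exists. First-order expansion of the
  stationarity condition shows $t_1^*$ increases when $L$ or $P_L$ is
  scaled up — the comparative-statics signature that separates the two
  regimes behaviourally.

Around the decision core, the package provides a simulator for a
virtual operant-conflict game (sequential exponential-lifetime tokens,
a three-level Poisson-hazard predator discretised into 20 ms activation
bins, pluggable agent policies), the trial-level analysis pipeline
(implicit-choice reconstruction, response-window filtering, two-stage
condition means, random-intercept trend tests), and an ideal-observer
inversion that reconstructs the threat prior implied by observed
latencies and predicts latencies forward from it.

## Worked example

Simulate eight decision-theoretic agents through the default game
(270 epochs, catch probabilities 0.1/0.2/0.3 per 100 ms of exposure)
and test the latency trends:

```r
library(aacbdt)
cfg <- task_config()
cfg$lambda2
#> [1] 1.053605 2.231436 3.566749

trials <- simulate_experiment(cfg, simple_bdt_agent(),
                              n_subjects = 8, seed = 2024)
trend_test(filter_latencies(trials), "approach")
#> Linear trend test on approach latencies (profiled GLS (random intercept, ML))
#>   n = 7240 observations, 8 subjects; df = (1, 7228)
#>             estimate        se      F         p
#> (Intercept)  0.81383 0.0009275 769912  0.00e+00
#> threat       0.11282 0.0009444  14271  0.00e+00
#> loss         0.06204 0.0008119   5840  0.00e+00
#> threat:loss -0.03379 0.0010188   1100 1.07e-224
#>   residual sd = 0.06356 s, subject-intercept sd = 0.001491 s
```

Approach latency rises by about 113 ms per threat level and 62 ms per
token at stake — the scenario-2 signature; under scenario-1 agents both
slopes are zero. Inverting latencies from noise-free agents recovers
the threat prior that generated them:

```r
sim <- simulate_experiment(cfg, example_bdt_agent(noise_sd = 0,
                                                  always_go = TRUE),
                           n_subjects = 8, seed = 77)
reconstruct_prior(sim)
#> Threat-prior reconstruction from approach latencies
#>
#> reconstructed threat prior (clamped linear derivative)
#>   derivative: min(-1.281 +1.28 t, 0) 1/s
#>   anchored at prior(0.798 s) = 0.198
#>
#> ideal-observer parameters
#>   desired tokens D: 3.317 3.225 3.444
#>   catch prob per movement P_C: 0.1111 0.1999 0.2833
#>   token prob per movement P_T: 0.5814
#>   level scales (mean/level catch rate): 1.784 0.991 0.699
#>
#>   14/14 condition cells in the fit; latency RMSE 10.3 ms
#>   interior optimum in 14/15 predicted conditions
```

The generating prior has derivative $\min(-1.35 + 1.35\,t_1,\, 0)$ and
value 0.2 at 0.74 s; the reconstruction recovers it to within a few
hundredths over the observed latency range and predicts the
per-condition mean latencies to about 10 ms RMS. `run_demo()` wires the
whole pipeline (simulate → analyse → reconstruct) and writes all tables
plus a reproducibility manifest; `inst/cli/aacbdt.R` exposes
`simulate` / `analyze` / `reconstruct` / `demo` subcommands for shell
use.

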