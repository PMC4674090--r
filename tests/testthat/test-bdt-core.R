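test_that("gain probability is the exponential survival function", {
  gp <- gain_prior(0.8)
  expect_equal(gain_probability(0, gp), 1)
  # oracle: survival = 1 - integral of the exponential density
  surv <- 1 - integrate(function(x) dexp(x, 0.8), 0, 1.25)$value
  expect_equal(gain_probability(1.25, gp), surv, tolerance = 1e-8)
  expect_equal(gain_probability(1.25, gp), exp(-1), tolerance = 1e-12)
  expect_equal(gain_probability(log(2) / 0.8, gp), 0.5)
  expect_error(gain_probability(-0.1, gp), "negative")
})

test_that("exposure-only loss probability and its rate inversion agree with the design", {
  expect_equal(loss_probability_scenario1(0, threat_scenario1(2)), 0)
  expect_equal(loss_probability_scenario1(0.1, threat_scenario1(1.0536)),
               0.1, tolerance = 1e-4)
  expect_equal(loss_probability_scenario1(0.1, threat_scenario1(3.5667)),
               0.3, tolerance = 1e-4)
  # inverse pair
  for (p in c(0.05, 0.1, 0.2, 0.3, 0.7)) {
    r <- rate_from_catch_probability(p, 0.1)
    expect_equal(loss_probability_scenario1(0.1, threat_scenario1(r)), p,
                 tolerance = 1e-12)
  }
  # small-probability linearisation
  expect_equal(rate_from_catch_probability(1e-6, 0.1), 1e-6 / 0.1,
               tolerance = 1e-5)
  expect_error(rate_from_catch_probability(0, 0.1), "strictly")
  expect_error(rate_from_catch_probability(1, 0.1), "strictly")
  expect_error(loss_probability_scenario1(-1, threat_scenario1(1)))
})

test_that("expected utility reduces to the gain term without threat and decreases under scenario 1", {
  gp <- gain_prior(0.8)
  # negligible-threat limit
  m0 <- bdt_model(G = 1, L = -1, gain = gp,
                  threat = threat_scenario1(1e-12), exposure = 0.1)
  tt <- seq(0, 2, by = 0.05)
  expect_equal(expected_utility(tt, m0), gain_probability(tt, gp),
               tolerance = 1e-9)
  # scenario 1: strictly decreasing in latency (finite differences)
  for (i in 1:5) {
    m <- random_scenario1_model()
    z <- expected_utility(tt, m)
    expect_true(all(diff(z) < 0))
  }
  # scenario-2 quadratic prior: interior maximum on a grid
  m2 <- bdt_model(G = 1, L = -2, gain = gp,
                  threat = quadratic_threat_prior(-1.1, 1.1, 0.7, 0.2))
  z2 <- expected_utility(tt, m2)
  expect_gt(which.max(z2), 1)
  expect_lt(which.max(z2), length(tt))
})

test_that("analytic utility derivative matches central finite differences", {
  set.seed(101)
  fd <- function(m, t, h = 1e-5)
    (expected_utility(t + h, m) - expected_utility(t - h, m)) / (2 * h)
  models <- c(replicate(5, random_scenario1_model(), simplify = FALSE),
              replicate(5, random_scenario2_model(), simplify = FALSE))
  # plus a motor-cost model
  models <- c(models, list(
    bdt_model(G = 1, L = -1, gain = gain_prior(0.8),
              threat = threat_scenario1(1.05), exposure = 0.1,
              motor_cost = list(c0 = 0.5, r = 2))))
  for (m in models) {
    tt <- seq(0.1, 1.2, length.out = 7)
    expect_equal(utility_derivative(tt, m), fd(m, tt),
                 tolerance = 1e-6)
  }
  # scenario 1 closed form
  m1 <- bdt_model(G = 2, L = -1, gain = gain_prior(0.7),
                  threat = threat_scenario1(2), exposure = 0.1)
  expect_equal(utility_derivative(0.4, m1), -2 * 0.7 * exp(-0.7 * 0.4),
               tolerance = 1e-12)
})

test_that("derivative vanishes at an interior optimum and changes sign around it", {
  set.seed(7)
  m <- random_scenario2_model()
  opt <- optimal_latency(m, interval = c(0, 2))
  expect_false(opt$boundary)
  expect_equal(utility_derivative(opt$t1, m), 0, tolerance = 1e-6)
  expect_gt(utility_derivative(opt$t1 - 0.05, m), 0)
  expect_lt(utility_derivative(opt$t1 + 0.05, m), 0)
})

test_that("scenario 1 always yields the left endpoint of the search interval", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_scenario1_model()
    opt <- optimal_latency(m, interval = c(0.15, 2), resolution = 0.005)
    expect_equal(opt$t1, 0.15)
    expect_true(opt$boundary)
  }
})

test_that("grid refinement is stable", {
  m <- bdt_model(G = 1, L = -2, gain = gain_prior(0.8),
                 threat = quadratic_threat_prior(-1.1, 1.1, 0.7, 0.2))
  coarse <- optimal_latency(m, c(0, 3), resolution = 0.01)
  fine <- optimal_latency(m, c(0, 3), resolution = 0.005)
  expect_lt(abs(fine$t1 - coarse$t1), 0.01)
})

test_that("assumption checks separate the two scenarios", {
  m1 <- random_scenario1_model()
  expect_error(optimal_latency(m1, c(0, -1)))
  a1 <- verify_assumptions(
    bdt_model(G = 1, L = -1, gain = gain_prior(0.8),
              threat = threat_prior(function(t) rep(0.2, length(t)),
                                    function(t) rep(0, length(t)),
                                    function(t) rep(0, length(t)))),
    interval = c(0.05, 1.5))
  expect_false(a1$a7)   # flat prior: no decay
  m2 <- bdt_model(G = 1, L = -2, gain = gain_prior(0.8),
                  threat = quadratic_threat_prior(-1.1, 1.1, 0.7, 0.2))
  a2 <- verify_assumptions(m2, interval = c(0.05, 0.95))
  expect_true(a2$a7 && a2$a8 && a2$a9)
  # prior decaying more slowly than the gain everywhere: no crossing,
  # and the maximiser must sit on the interval boundary
  slow <- quadratic_threat_prior(-0.05, 0.01, anchor_t = 0, anchor_p = 0.6)
  m3 <- bdt_model(G = 1, L = -1, gain = gain_prior(0.8), threat = slow)
  a3 <- verify_assumptions(m3, interval = c(0.05, 1.5))
  expect_false(a3$a9)
  expect_true(optimal_latency(m3, c(0.05, 1.5))$boundary)
})

test_that("scaling loss magnitude or probability delays the optimum (vs grid oracle)", {
  set.seed(23)
  for (i in 1:3) {
    m <- random_scenario2_model()
    base <- grid_argmax(m, c(0, 2), 0.001)
    for (k in c(1.05, 1.1, 1.2)) {
      for (mode in c("loss_magnitude", "loss_probability")) {
        if (mode == "loss_probability" &&
            k * m$threat$value(0) > 1) next
        sh <- latency_shift_under_scaling(m, k, mode, interval = c(0, 2))
        expect_gte(sh$shift, 0)
        # independent brute-force check of the scaled optimum
        m_scaled <- m
        if (mode == "loss_magnitude") m_scaled$L <- k * m$L
        else m_scaled$threat <- scale_threat_prior(m$threat, k)
        oracle <- grid_argmax(m_scaled, c(0, 2), 0.001)
        expect_equal(sh$t1_scaled, oracle, tolerance = 2e-3)
        expect_gte(oracle - base, -1e-9)
      }
    }
    expect_equal(latency_shift_under_scaling(m, 1, "loss_magnitude",
                                             interval = c(0, 2))$shift, 0)
  }
})

test_that("probability scaling refuses to push the prior past 1", {
  pr <- quadratic_threat_prior(-1.1, 1.1, 0.7, 0.2)   # value(0) ~ 0.8
  m <- bdt_model(G = 1, L = -2, gain = gain_prior(0.8), threat = pr)
  expect_error(latency_shift_under_scaling(m, 2, "loss_probability",
                                           interval = c(0, 2)),
               "exceeds probability 1")
})

test_that("a motor cost yields a non-trivial optimum that ignores loss but tracks gain", {
  gp <- gain_prior(0.8)
  m <- bdt_model(G = 1, L = -1, gain = gp,
                 threat = threat_scenario1(1.05), exposure = 0.1,
                 motor_cost = list(c0 = 2, r = 3))
  opt <- optimal_latency(m, c(0, 3))
  expect_false(opt$boundary)            # urgency cost creates an optimum
  # loss scaling leaves it untouched
  sh <- latency_shift_under_scaling(m, 1.5, "loss_magnitude", c(0, 3))
  expect_equal(sh$shift, 0, tolerance = 1e-9)
  shp <- latency_shift_under_scaling(m, 1.5, "loss_probability", c(0, 3))
  expect_equal(shp$shift, 0, tolerance = 1e-9)
  # but gain scaling moves it
  m_g <- m; m_g$G <- 1.5 * m$G
  expect_gt(abs(optimal_latency(m_g, c(0, 3))$t1 - opt$t1), 1e-3)
})

test_that("optimal latency is invariant under common utility rescaling", {
  m <- bdt_model(G = 1, L = -2, gain = gain_prior(0.8),
                 threat = quadratic_threat_prior(-1.1, 1.1, 0.7, 0.2))
  m_scaled <- m; m_scaled$G <- 3; m_scaled$L <- -6
  expect_equal(optimal_latency(m, c(0, 2))$t1,
               optimal_latency(m_scaled, c(0, 2))$t1, tolerance = 1e-9)
})
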