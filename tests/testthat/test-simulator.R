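test_that("simulations are reproducible and extendable in cell count", {
  d <- make_degradation_model("exponential", gamma = 1/60)
  cc <- cell_config("doubly_stochastic", k_on = 0.02, k_off = 0.02,
                    kappa = kappa_modulator_constant(0.1),
                    degradation = d, horizon = 300, burn_in = 50)
  a <- simulate_doubly_stochastic(cc, 50, seed = 5, log_events = TRUE)
  b <- simulate_doubly_stochastic(cc, 50, seed = 5, log_events = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
  # per-cell streams: growing the population leaves existing cells untouched
  c80 <- simulate_doubly_stochastic(cc, 80, seed = 5)
  expect_identical(c80$counts[1:50], a$counts)
  d2 <- simulate_doubly_stochastic(cc, 50, seed = 6)
  expect_false(identical(d2$counts, a$counts))
})

test_that("configuration contracts are enforced", {
  d <- make_degradation_model("exponential", gamma = 1/60)
  expect_error(cell_config("doubly_stochastic",
                           kappa = kappa_modulator_constant(0.1),
                           degradation = d, horizon = 10, burn_in = 20),
               "burn_in")
  expect_error(cell_config("doubly_stochastic", degradation = d, horizon = 10),
               "modulator")
  expect_error(cell_config("mechanistic", tau1 = -1, tau2 = 1, b = 1,
                           degradation = d, horizon = 10), "tau1")
  expect_error(estimate_noise(3), "at least 2")
})

test_that("noise estimator handles degenerate and Poisson counts", {
  flat <- estimate_noise(rep(4L, 100))
  expect_equal(flat$var, 0)
  expect_equal(flat$q_over_n, -1/4)
  set.seed(31)
  pois <- estimate_noise(rpois(4000, 6))
  expect_lt(abs(pois$fano - 1), 3 * pois$se[["fano"]])
  expect_lt(abs(pois$mean - 6), 3 * pois$se[["mean"]])
})

test_that("constant-rate transcription is Poisson for a non-exponential
           lifetime", {
  cc <- cell_config("doubly_stochastic", kappa = kappa_modulator_constant(0.2),
                    degradation = make_degradation_model("two_state_super"),
                    horizon = 300)
  en <- estimate_noise(simulate_doubly_stochastic(cc, 3000, seed = 17))
  expect_lt(abs(en$fano - 1), 3 * en$se[["fano"]])
  expect_lt(abs(en$mean - 0.2 * 25.8), 3 * en$se[["mean"]])
})

test_that("telegraph simulation reproduces the closed-form Fano factor", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  cc <- cell_config("doubly_stochastic", k_on = 1/120, k_off = 1/120,
                    kappa = kappa_modulator_constant(0.05),
                    degradation = d, horizon = 1500)
  en <- estimate_noise(simulate_doubly_stochastic(cc, 4000, seed = 7))
  expect_lt(abs(en$fano - 2), 3 * en$se[["fano"]])
})

test_that("modulated-rate simulation matches the stationary decomposition", {
  d <- make_degradation_model("exponential", gamma = 1/30)
  m <- transcription_model("model_III", kappa_mean = 0.3, k_on = 0.02,
                           k_off = 0.02,
                           kappa_tcf = parametric_env_tcf("exponential",
                                                          eta2 = 2, decay = 0.1))
  nd <- steady_state_noise(m, d)
  en <- sim_model3_noise(m, d, 4000, horizon = 400, seed = 23)
  expect_lt(abs(en$q_over_n - nd$q_over_n), 3 * en$se[["q_over_n"]])
  expect_lt(abs(en$mean - nd$mean_n), 3 * en$se[["mean"]])
})

test_that("event-stream rate TCF estimation matches renewal closed forms", {
  d <- make_degradation_model("exponential", gamma = 0.05)
  # Poisson stream: zero covariance at positive lags
  ccp <- cell_config("mechanistic", tau1 = 2, tau2 = 0.02, b = 0.02,
                     degradation = d, horizon = 2100, burn_in = 100)
  simp <- simulate_mechanistic(ccp, 100, seed = 3, log_events = TRUE)
  estp <- estimate_rate_tcf(simp, bin_width = 0.5, max_lag = 6)
  sep <- tcf_estimate_se(estp, seed = 1)
  expect_true(all(abs(estp$cov[-1]) < 3 * sep$se[-1]))

  # Erlang-2 stream: cov(t) = -(mu^2/4) exp(-2 mu t), compared bin-averaged
  mu <- 1
  cce <- cell_config("mechanistic", tau1 = 1/mu, tau2 = 1/mu, b = 1/mu,
                     degradation = d, horizon = 2100, burn_in = 100)
  sime <- simulate_mechanistic(cce, 150, seed = 11, log_events = TRUE)
  este <- estimate_rate_tcf(sime, bin_width = 0.1, max_lag = 5)
  see <- tcf_estimate_se(este, seed = 1)
  lo <- este$grid - 0.05; hi <- este$grid + 0.05
  exact <- -(mu / 8) * (exp(-2 * mu * lo) - exp(-2 * mu * hi)) / 0.1
  z <- (este$cov - exact) / see$se
  expect_lt(abs(z[1]), 3)
  expect_lt(mean(z^2), 2)
  expect_lt(max(abs(z)), 4.5)
})

test_that("near-clockwork transcription is strongly sub-Poisson and the
           exponential limit is Poisson", {
  d <- make_degradation_model("exponential", gamma = 0.2)
  clock <- cell_config("mechanistic", tau1 = 0.02, tau2 = 1, b = 0.005,
                       degradation = d, horizon = 60)
  enc <- estimate_noise(simulate_mechanistic(clock, 2000, seed = 13))
  expect_lt(enc$fano + 3 * enc$se[["fano"]], 0.8)
  pois <- cell_config("mechanistic", tau1 = 1, tau2 = 0.005, b = 0.005,
                      degradation = d, horizon = 60)
  enp <- estimate_noise(simulate_mechanistic(pois, 2000, seed = 13))
  expect_lt(abs(enp$fano - 1), 3.5 * enp$se[["fano"]])
})

test_that("rate-TCF estimator rejects empty logs and odd lag grids", {
  d <- make_degradation_model("exponential", gamma = 0.05)
  cc <- cell_config("doubly_stochastic", kappa = kappa_modulator_constant(0.1),
                    degradation = d, horizon = 50)
  sim <- simulate_doubly_stochastic(cc, 5, seed = 1)   # no event log
  expect_error(estimate_rate_tcf(sim, 0.1, 5), "log_events")
  sim2 <- simulate_doubly_stochastic(cc, 5, seed = 1, log_events = TRUE)
  expect_error(estimate_rate_tcf(sim2, 0.3, 1), "multiple")
})
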