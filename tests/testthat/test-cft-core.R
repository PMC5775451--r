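test_that("mean trajectory follows the convolution closed form", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  expect_equal(mean_trajectory(0.05, d, 0), 0)
  # constant rate, exponential decay: (R/gamma)(1 - exp(-gamma t))
  for (tt in c(30, 120, 600)) {
    expect_equal(mean_trajectory(0.05, d, tt),
                 6 * (1 - exp(-tt / 120)), tolerance = 1e-8)
  }
  expect_equal(mean_trajectory(0.05, d, 5000), 6, tolerance = 1e-6)
  expect_error(mean_trajectory(0.05, d, -1), "non-negative")
})

test_that("steady-state mean is set by the mean lifetime alone", {
  # equal mean lifetime, different lifetime fluctuations: identical mean
  models <- list(make_degradation_model("michaelis_menten"),
                 make_degradation_model("exponential", gamma = 1/25.8),
                 make_degradation_model("two_state_super"))
  means <- vapply(models, function(d) mean_trajectory(0.1, d, 2000), 0)
  expect_equal(means, rep(0.1 * 25.8, 3), tolerance = 1e-6)
})

test_that("zero rate covariance gives Poisson statistics for any lifetime", {
  zero_cov <- function(t1, t2) 0
  for (d in list(make_degradation_model("michaelis_menten"),
                 make_degradation_model("exponential", gamma = 1/25.8),
                 make_degradation_model("two_state_super"))) {
    vt <- variance_trajectory(0.1, zero_cov, d, 150)
    expect_equal(vt$variance, vt$mean, tolerance = 1e-8)
  }
})

test_that("asymmetric rate covariance is rejected", {
  d <- make_degradation_model("exponential", gamma = 0.01)
  expect_error(variance_trajectory(0.1, function(t1, t2) t1 - t2, d, 10),
               "symmetric")
})

test_that("finite-time variance converges to the stationary decomposition", {
  # telegraph model: cov(t1,t2) = kappa^2 eta_xi^2 <xi>^2 exp(-(kon+koff)|dt|)
  kon <- koff <- 1/120; gamma <- 1/120; kappa <- 0.05
  d <- make_degradation_model("exponential", gamma = gamma)
  xi <- switching_tcf(kon, koff)
  rate2 <- (kappa * xi$xi_mean)^2 * xi$eta2
  cov <- function(t1, t2) rate2 * exp(-(kon + koff) * abs(t1 - t2))
  vt <- variance_trajectory(kappa * xi$xi_mean, cov, d, 2500, n = 401)
  m <- transcription_model("model_II", kappa_mean = kappa, k_on = kon,
                           k_off = koff)
  nd <- steady_state_noise(m, d)
  expect_equal(vt$variance / vt$mean, nd$fano, tolerance = 2e-3)
})

test_that("susceptibility identities hold", {
  gamma <- 1/120
  d <- make_degradation_model("exponential", gamma = gamma)
  expect_equal(susceptibility(d, constant_tcf()), 1, tolerance = 1e-12)
  lam <- 306 * gamma
  tc <- parametric_env_tcf("exponential", eta2 = 1, decay = lam)
  expect_equal(susceptibility(d, tc), gamma / (gamma + lam), tolerance = 1e-8)
  # white-noise limit
  expect_lt(susceptibility(d, parametric_env_tcf("exponential", 1, 1e7)), 1e-4)
  # bilinear: exponential-exponential closed form and definitional identity
  l1 <- parametric_env_tcf("exponential", 1, 0.02)
  l2 <- parametric_env_tcf("exponential", 1, 0.05)
  expect_equal(bilinear_susceptibility(d, l1, l2),
               gamma / (gamma + 0.07), tolerance = 1e-10)
  expect_equal(bilinear_susceptibility(d, l1, l2),
               susceptibility(d, product_tcf(l1, l2)), tolerance = 1e-10)
  expect_equal(bilinear_susceptibility(d, constant_tcf(), constant_tcf()), 1,
               tolerance = 1e-12)
})

test_that("susceptibilities stay in [-1, 1] for random lifetime/TCF pairs", {
  set.seed(5)
  for (i in 1:100) {
    d <- random_phase_type()
    tc <- random_env_tcf()
    chi <- susceptibility(d, tc)
    expect_lte(abs(chi), 1 + 1e-12)
  }
})

test_that("resolvent and adaptive-quadrature susceptibilities agree", {
  set.seed(9)
  for (i in 1:25) {
    d <- random_phase_type()
    tc <- random_env_tcf()
    expect_equal(susceptibility(d, tc),
                 susceptibility(d, tc, method = "quadrature"),
                 tolerance = 1e-8)
  }
})

test_that("delta lifetimes integrate TCFs over the finite support", {
  tau <- 40; lam <- 0.05
  d <- lifetime_delta(tau)
  tc <- parametric_env_tcf("exponential", 1, lam)
  closed <- 2 * (lam * tau - 1 + exp(-lam * tau)) / (lam * tau)^2
  expect_equal(susceptibility(d, tc), closed, tolerance = 1e-10)
  expect_equal(susceptibility(d, constant_tcf()), 1, tolerance = 1e-12)
})

test_that("telegraph steady state matches the closed-form Fano factor", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  m <- transcription_model("model_II", kappa_mean = 0.05, k_on = 1/120,
                           k_off = 1/120)
  nd <- steady_state_noise(m, d)
  expect_equal(nd$fano, 2, tolerance = 1e-10)
  expect_equal(nd$mean_n, 3, tolerance = 1e-12)
  # additivity of the decomposition
  expect_equal(nd$eta2_n,
               nd$poisson_term + nd$term_xi + nd$term_kappa + nd$term_bilinear)
  expect_equal(nd$q_over_n, nd$eta2_n - 1 / nd$mean_n)
})

test_that("constant-rate and telegraph reductions of the full model hold", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  m1 <- transcription_model("model_I", kappa_mean = 0.05)
  nd <- steady_state_noise(m1, d)
  expect_equal(nd$mean_n, 6)
  expect_equal(nd$q_over_n, 0)
  expect_equal(nd$eta2_n, 1 / 6)
})

test_that("stationary decomposition equals independent quadrature of the
           variance relation for random parameterizations", {
  set.seed(21)
  for (i in 1:20) {
    d <- random_phase_type()
    kon <- runif(1, 0.005, 0.1); koff <- runif(1, 0.001, 0.1)
    kt <- parametric_env_tcf("exponential", eta2 = runif(1, 0.5, 20),
                             decay = runif(1, 0.01, 1))
    m <- transcription_model("model_III", kappa_mean = runif(1, 0.02, 0.3),
                             k_on = kon, k_off = koff, kappa_tcf = kt)
    a <- steady_state_noise(m, d)
    b <- steady_state_noise(m, d, method = "quadrature")
    expect_equal(a$eta2_n, b$eta2_n, tolerance = 1e-8)
  }
})

test_that("non-Poisson noise ordering across lifetime models at fixed mean", {
  m <- fig5_model()
  q <- vapply(list(make_degradation_model("michaelis_menten"),
                   make_degradation_model("exponential", gamma = 1/25.8),
                   make_degradation_model("two_state_super")),
              function(d) steady_state_noise(m, d)$q_over_n, 0)
  # sub-Poisson decay noisiest, super-Poisson decay quietest
  expect_gt(q[1], q[2])
  expect_gt(q[2], q[3])
})
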