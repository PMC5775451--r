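test_that("population noise combines copy number and correlation terms", {
  # single-copy reduction
  one <- copy_number_model(1)
  sn <- steady_state_noise(transcription_model("model_I", kappa_mean = 0.05),
                           make_degradation_model("exponential", gamma = 1/120))
  pop <- population_noise(sn, one, 0)
  expect_equal(pop$q_over_n, sn$q_over_n)
  expect_equal(pop$mean_n, sn$mean_n)

  # hand enumeration: g in {1,2} equiprobable, Q1/n1 = 0.5, C_n = 0.1
  cp <- copy_number_model(c(1, 2))
  expect_equal(cp$mean, 1.5)
  expect_equal(cp$eta2_g, (0.25) / 2.25)
  expect_equal(cp$g_fact2, 1)
  fake <- sn; fake$q_over_n <- 0.5
  expect_equal(population_noise(fake, cp, 0.1)$q_over_n,
               0.5 / 1.5 + 1 / 9 + 0.1 / 2.25, tolerance = 1e-12)
  # contract: C_n may not exceed the single-copy non-Poisson noise
  expect_warning(population_noise(fake, cp, 0.6), "exceeds")
  expect_error(population_noise(fake, cp, 0.6, strict = TRUE), "exceeds")
})

test_that("polymerase-sharing correlation limits are respected", {
  # weak binding: correlation approaches the full RNAP noise
  set.seed(2)
  nrp <- c(60, 100, 140); p <- c(0.25, 0.5, 0.25)
  weak <- rnap_sharing_correlation(rnap_environment(nrp, p, K = 1e-9))
  eta2 <- weak$eta2_n_rp
  expect_equal(weak$approx, eta2, tolerance = 1e-6)
  expect_equal(weak$exact, eta2, tolerance = 1e-3)
  # printed example: eta2 = 0.1, Kbar Nbar = 1 -> approximation 0.025
  env1 <- rnap_environment(c(50, 100, 150), c(0.25, 0.5, 0.25), K = 1/100)
  ex <- rnap_sharing_correlation(env1)
  expect_equal(ex$approx, ex$eta2_n_rp / 4, tolerance = 1e-12)
  # saturated promoter: correlation vanishes
  sat <- rnap_sharing_correlation(rnap_environment(nrp, p, K = 1e6))
  expect_lt(sat$exact, 1e-9)
  expect_gte(ex$exact, 0)
  # exact enumeration approaches the approximation for weak RNAP noise
  narrow <- c(95, 100, 105)
  pn <- c(1, 2, 1) / 4
  envn <- rnap_environment(narrow, pn, K = 1/100)
  rn <- rnap_sharing_correlation(envn)
  expect_lt(rn$eta2_n_rp, 0.01)
  expect_lt(abs(rn$exact - rn$approx) / rn$approx, 0.05)
})

test_that("linear-RNAP model noise is mean independent", {
  cp <- copy_number_model(c(1, 2, 3), c(0.3, 0.4, 0.3))
  env <- rnap_environment(c(50, 150), c(0.5, 0.5), K = 0.01)
  q <- simple_rnap_model_noise(cp, env)
  expect_equal(q, env$eta2_n_rp / cp$mean + cp$eta2_g, tolerance = 1e-12)
  # deterministic everything: no noise
  expect_equal(simple_rnap_model_noise(copy_number_model(2),
                                       rnap_environment(100, K = 0.01)), 0)
})

test_that("constitutive model reduces to the single-gene model without RNAP
           spread or affinity fluctuation", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  kt <- parametric_env_tcf("exponential", eta2 = 5, decay = 0.5)
  env <- rnap_environment(100, K = 0.02)   # deterministic RNAP
  cn <- constitutive_noise(env, kt, d, copy_number_model(1), k_tx_mean = 0.3,
                           affinity_fluctuation = "off")
  theta <- 0.02 * 100 / (1 + 0.02 * 100)
  m3 <- transcription_model("model_III", kappa_mean = theta * 0.3,
                            k_on = 1, k_off = 0, kappa_tcf = kt)
  ref <- steady_state_noise(m3, d)
  expect_equal(cn$single$eta2_n, ref$eta2_n, tolerance = 1e-12)
  expect_equal(cn$c_n, 0)
})

test_that("fast affinity switching removes the dichotomous-K contribution", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  kt <- parametric_env_tcf("exponential", eta2 = 5, decay = 0.5)
  cp <- copy_number_model(1)
  base <- constitutive_noise(rnap_environment(100, K0 = 0.02), kt, d, cp,
                             k_tx_mean = 0.3, affinity_fluctuation = "off")
  slow <- constitutive_noise(rnap_environment(100, K0 = 0.02, k_open = 0.005,
                                              k_close = 0.005),
                             kt, d, cp, 0.3, "on")
  fast <- constitutive_noise(rnap_environment(100, K0 = 0.02, k_open = 500,
                                              k_close = 500),
                             kt, d, cp, 0.3, "on")
  # same occupied-state statistics; only the switching speed differs
  excess_slow <- slow$single$q_over_n - base$single$q_over_n
  excess_fast <- fast$single$q_over_n - base$single$q_over_n
  expect_gt(excess_slow, 0.01)
  expect_lt(excess_fast, 1e-3)
})

test_that("copy-number and correlation terms are flat along a k_off sweep", {
  d <- make_degradation_model("exponential", gamma = 1/120)
  kt <- parametric_env_tcf("exponential", eta2 = 30, decay = 306/120)
  cp <- copy_number_model(c(1, 2), c(0.4, 0.6))
  c_n <- 0.02
  terms <- vapply(c(0.001, 0.01, 0.1, 1), function(koff) {
    m <- transcription_model("model_III", kappa_mean = 1/12, k_on = 0.01,
                             k_off = koff, kappa_tcf = kt)
    pop <- population_noise(steady_state_noise(m, d), cp, c_n)
    pop$term_copy + pop$term_corr
  }, 0)
  expect_equal(terms, rep(terms[1], 4), tolerance = 1e-12)
})
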