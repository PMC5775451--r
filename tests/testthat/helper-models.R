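# shared fixture builders for the test suite (all generated in code)

# random valid phase-type lifetime with 1-3 transient states
random_phase_type <- function() {
  m <- sample(1:3, 1)
  Tm <- matrix(0, m, m)
  if (m > 1) {
    off <- matrix(stats::runif(m * m, 0, 0.2), m, m)
    diag(off) <- 0
    Tm <- off
  }
  exit <- stats::runif(m, 0.02, 0.5)
  diag(Tm) <- -(rowSums(Tm) + exit)
  a <- stats::runif(m); a <- a / sum(a)
  lifetime_phase_type(a, Tm)
}

# random closed-form TCF (exponential or damped cosine)
random_env_tcf <- function() {
  if (stats::runif(1) < 0.5) {
    parametric_env_tcf("exponential", eta2 = stats::runif(1, 0, 5),
                       decay = stats::runif(1, 0.005, 2))
  } else {
    parametric_env_tcf("damped_cosine", eta2 = stats::runif(1, 0, 5),
                       decay = stats::runif(1, 0.01, 2),
                       freq = stats::runif(1, 0.05, 3))
  }
}

# reference Model III transcription settings used in the lifetime-randomness
# studies: exponential hidden-rate TCF, symmetric gene switching
fig5_model <- function(kappa_mean = 0.2) {
  transcription_model("model_III", kappa_mean = kappa_mean,
                      k_on = 0.01, k_off = 0.01,
                      kappa_tcf = parametric_env_tcf("exponential", eta2 = 30,
                                                     decay = 306 / 120))
}

# closed-form telegraph Fano factor (independent oracle)
telegraph_fano <- function(kappa, k_on, k_off, gamma) {
  1 + kappa * k_off / ((k_on + k_off) * (k_on + k_off + gamma))
}

# simulate a Model III population and estimate noise
sim_model3_noise <- function(model, dist, n_cells, horizon, seed,
                             rate_scale = 1) {
  kt <- model$kappa_tcf
  cc <- cell_config("doubly_stochastic",
                    k_on = model$xi_tcf$k_on, k_off = model$xi_tcf$k_off,
                    kappa = kappa_modulator_exponential(model$kappa_mean,
                                                        kt$eta2, Re(kt$terms$z[1])),
                    degradation = dist, horizon = horizon)
  estimate_noise(simulate_doubly_stochastic(cc, n_cells, seed = seed,
                                            rate_scale = rate_scale))
}
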