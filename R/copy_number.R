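#' Gene copy-number models and polymerase-sharing environments
#'
#' Cell populations carry a stochastic gene copy number `g` (static on the
#' transcription timescale) and share global environmental variables — most
#' importantly the RNA-polymerase copy number `N_Rp` — across gene copies,
#' which correlates the mRNA outputs of distinct copies.
#'
#' @param g support values (non-negative integers).
#' @param p probabilities (sum to 1).
#' @return a `cft_copies` with mean, relative variance `eta2_g`, Fano factor
#'   `F_g` and factorial moment `<g(g-1)>`.
#' @export
copy_number_model <- function(g, p = rep(1 / length(g), length(g))) {
  if (length(g) != length(p)) stop("support and probabilities differ in length")
  if (any(g < 0) || any(g != round(g))) stop("copy numbers must be non-negative integers")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop("probabilities must be non-negative and sum to 1")
  m <- sum(g * p)
  if (m <= 0) stop("mean copy number must be positive")
  v <- sum(g^2 * p) - m^2
  structure(list(g = g, p = p, mean = m, var = v,
                 eta2_g = v / m^2, F_g = v / m,
                 g_fact2 = sum(g * (g - 1) * p)),
            class = "cft_copies")
}

#' RNA-polymerase environment of a constitutive promoter
#'
#' Discrete distribution of the cellular RNAP copy number (static per cell)
#' plus the promoter's binding affinity: either a constant `K` or a
#' dichotomous stochastic affinity switching between 0 and `K0` at rates
#' `k_open` (to `K0`) and `k_close` (to 0), modelling conformational dynamics
#' of the promoter DNA. Units of `K` are inverse RNAP copies, so `K * N_Rp`
#' is dimensionless and the promoter occupancy is
#' `theta = K N_Rp / (1 + K N_Rp)`.
#'
#' @param n_rp RNAP copy-number support.
#' @param p probabilities.
#' @param K constant affinity (per RNAP copy).
#' @param K0 dichotomous affinity high value.
#' @param k_open,k_close dichotomous switch rates in Hz.
#' @export
rnap_environment <- function(n_rp, p = rep(1 / length(n_rp), length(n_rp)),
                             K = NULL, K0 = NULL,
                             k_open = NULL, k_close = NULL) {
  if (!length(n_rp)) stop("empty RNAP support")
  if (length(n_rp) != length(p)) stop("support and probabilities differ in length")
  if (any(n_rp < 0)) stop("RNAP copy numbers must be non-negative")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (is.null(K) && is.null(K0)) stop("supply a constant K or a dichotomous K0")
  m <- sum(n_rp * p)
  v <- sum(n_rp^2 * p) - m^2
  structure(list(n_rp = n_rp, p = p, K = K, K0 = K0,
                 k_open = k_open, k_close = k_close,
                 mean_n_rp = m, eta2_n_rp = v / m^2),
            class = "rnap_environment")
}

#' Population noise from copy-number variation and inter-copy correlation
#'
#' Combines the single-copy non-Poisson noise with copy-number variation and
#' the environment-induced correlation `C_n` between copies:
#' \deqn{Q_n/\langle n\rangle = \langle g\rangle^{-1} Q_{n,1}/\langle n\rangle_1
#'   + \eta_g^2 + \frac{\langle g(g-1)\rangle}{\langle g\rangle^2} C_n.}
#' The last two terms do not depend on the single-copy mean. `C_n` cannot
#' exceed the single-copy non-Poisson noise; violating that contract raises a
#' warning (or an error with `strict = TRUE`).
#'
#' @param single a `cft_noise` for one gene copy.
#' @param copies a `cft_copies`.
#' @param c_n mean-scaled inter-copy correlation (dimensionless).
#' @param strict error instead of warning when `c_n` exceeds the single-copy
#'   non-Poisson noise.
#' @return a `cft_noise` for the population, with extra fields
#'   `term_single`, `term_copy`, `term_corr`.
#' @export
population_noise <- function(single, copies, c_n = 0, strict = FALSE) {
  stopifnot(inherits(single, "cft_noise"), inherits(copies, "cft_copies"))
  if (c_n > single$q_over_n + 1e-12) {
    msg <- sprintf("C_n (%.4g) exceeds the single-copy non-Poisson noise (%.4g)",
                   c_n, single$q_over_n)
    if (strict) stop(msg) else warning(msg)
  }
  mean_n <- copies$mean * single$mean_n
  term_single <- single$q_over_n / copies$mean
  term_copy <- copies$eta2_g
  term_corr <- copies$g_fact2 / copies$mean^2 * c_n
  q <- term_single + term_copy + term_corr
  out <- new_noise(mean_n, 1 / mean_n)
  out$term_single <- term_single
  out$term_copy <- term_copy
  out$term_corr <- term_corr
  out$q_over_n <- q
  out$eta2_n <- q + 1 / mean_n
  out$fano <- mean_n * out$eta2_n
  out
}

#' Inter-copy correlation induced by RNAP sharing
#'
#' The mean-scaled correlation between the mRNA outputs of two gene copies
#' sharing a static per-cell RNAP level, computed two ways: the second-order
#' approximation `eta2_NRp / (1 + Kbar Nbar)^2` and the exact enumeration
#' `Var(theta)/<theta>^2` over the discrete RNAP support (copies conditionally
#' independent given the cell's RNAP level).
#'
#' @param env an `rnap_environment` with a constant `K` (or `K0`, used as the
#'   occupied-state affinity).
#' @return list with `approx`, `exact` and `eta2_n_rp`.
#' @export
rnap_sharing_correlation <- function(env) {
  stopifnot(inherits(env, "rnap_environment"))
  K <- if (!is.null(env$K)) env$K else env$K0
  theta <- K * env$n_rp / (1 + K * env$n_rp)
  tm <- sum(theta * env$p)
  tv <- sum(theta^2 * env$p) - tm^2
  list(approx = env$eta2_n_rp / (1 + K * env$mean_n_rp)^2,
       exact = if (tm > 0) tv / tm^2 else 0,
       eta2_n_rp = env$eta2_n_rp)
}

#' Non-Poisson noise of the linear-in-RNAP transcription model
#'
#' For Poisson transcription with rate proportional to the shared RNAP level,
#' `Q_n/<n> = <g>^{-1} eta2_NRp + eta2_g`, independent of the mean mRNA
#' number.
#'
#' @param copies a `cft_copies`.
#' @param env an `rnap_environment`.
#' @export
simple_rnap_model_noise <- function(copies, env) {
  stopifnot(inherits(copies, "cft_copies"), inherits(env, "rnap_environment"))
  env$eta2_n_rp / copies$mean + copies$eta2_g
}

#' Noise of constitutive expression with promoter-occupancy saturation
#'
#' Single-copy transcription rate
#' `R_1 = [K N_Rp / (1 + K N_Rp)] k_TX(Gamma)`: the RNAP level is static per
#' cell (handled as a mixture over cells), the hidden-environment factor
#' `k_TX` fluctuates with TCF `kappa_tcf`, and — with
#' `affinity_fluctuation = "on"` — the binding affinity `K` is a fast
#' dichotomous variable (0 or `K0`), which maps onto the gene-switching
#' factor of the steady-state decomposition with switch rates
#' `k_open`/`k_close`. With affinity fluctuation off and a deterministic RNAP
#' level this reduces structurally to the environment-coupled telegraph-free
#' model.
#'
#' @param env an `rnap_environment`.
#' @param kappa_tcf `cft_tcf` of the `k_TX` factor.
#' @param dist a `cft_lifetime`.
#' @param copies a `cft_copies`.
#' @param k_tx_mean mean of `k_TX` in Hz.
#' @param affinity_fluctuation `"off"` or `"on"`.
#' @return list: `population` (a `cft_noise`), `single` (marginal single-copy
#'   `cft_noise` mixed over RNAP), `c_n` (exact), `per_n` (per-RNAP-level
#'   decompositions).
#' @export
constitutive_noise <- function(env, kappa_tcf, dist, copies, k_tx_mean,
                               affinity_fluctuation = c("off", "on")) {
  stopifnot(inherits(env, "rnap_environment"))
  affinity_fluctuation <- match.arg(affinity_fluctuation)
  if (affinity_fluctuation == "on") {
    if (is.null(env$k_open) || is.null(env$k_close))
      stop("affinity fluctuation requires k_open and k_close switch rates")
    K <- env$K0
    k_on <- env$k_open; k_off <- env$k_close
  } else {
    K <- if (!is.null(env$K)) env$K else env$K0
    k_on <- 1; k_off <- 0    # degenerate switch: always occupied-affinity
  }
  theta <- K * env$n_rp / (1 + K * env$n_rp)
  per_n <- lapply(seq_along(env$n_rp), function(i) {
    if (theta[i] <= 0) return(NULL)
    m <- transcription_model("model_III",
                             kappa_mean = theta[i] * k_tx_mean,
                             k_on = k_on, k_off = k_off,
                             kappa_tcf = kappa_tcf)
    steady_state_noise(m, dist)
  })
  keep <- !vapply(per_n, is.null, TRUE)   # zero-occupancy cells produce 0 mRNA
  means <- vapply(per_n[keep], function(x) x$mean_n, 0)
  vars <- vapply(per_n[keep], function(x) x$eta2_n * x$mean_n^2, 0)
  mean_1 <- sum(env$p[keep] * means)
  var_1 <- sum(env$p[keep] * vars) + sum(env$p[keep] * means^2) - mean_1^2
  single <- new_noise(mean_1, 1 / mean_1)
  single$eta2_n <- var_1 / mean_1^2
  single$fano <- var_1 / mean_1
  single$q_over_n <- single$eta2_n - 1 / mean_1
  # inter-copy correlation from the shared static RNAP level
  c_n <- (sum(env$p[keep] * means^2) - mean_1^2) / mean_1^2
  pop <- population_noise(single, copies, c_n)
  list(population = pop, single = single, c_n = c_n, per_n = per_n)
}
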