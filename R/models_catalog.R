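#' Named transcription models
#'
#' Validated constructors for the transcription model zoo:
#' * `model_I` — constant-rate (Poisson) transcription, rate `kappa_mean`.
#' * `model_II` — telegraph: two-state gene switching at rates
#'   `k_on`/`k_off`, constant active-state rate `kappa_mean`.
#' * `model_III` — telegraph switching with an environment-coupled
#'   active-state rate whose fluctuation is represented only through its TCF
#'   (`kappa_tcf`).
#' * `constitutive_a`/`constitutive_b` — constitutive promoter with
#'   transcription rate `[K N_Rp / (1 + K N_Rp)] k_TX`; in `b` the binding
#'   affinity `K` is a dichotomous stochastic variable (0 or `K0`); requires
#'   an `rnap_environment`.
#' * `mechanistic` — renewal transcription of an always-active gene:
#'   exponential initial binding (mean `tau1`), gamma initiation (mean `tau2`,
#'   dispersion `b`), deterministic elongation delay `tau3`, with promoter
#'   occlusion (no re-binding until initiation completes). Its mean rate is
#'   derived as `1/(tau1 + tau2)` and is read-only.
#'
#' The reduction chain holds by construction: `model_III` with a zero-noise
#' `kappa_tcf` equals `model_II`, and `model_II` with `k_off = 0` equals
#' `model_I`.
#'
#' @param family model family name.
#' @param kappa_mean mean active-gene transcription rate in Hz
#'   (for `constitutive_*`: mean of `k_TX`).
#' @param k_on,k_off gene-state switching rates in Hz (telegraph families).
#' @param kappa_tcf a `cft_tcf` for the active-gene rate factor
#'   (required for `model_III`; optional for constitutive families).
#' @param env an `rnap_environment` (constitutive families).
#' @param tau1,tau2,b,tau3 mechanistic step parameters in seconds.
#' @return a `cft_model`.
#' @examples
#' m <- transcription_model("model_I", kappa_mean = 0.05)
#' d <- make_degradation_model("exponential", gamma = 1/120)
#' steady_state_noise(m, d)$mean_n  # 6 copies
#' @export
transcription_model <- function(family = c("model_I", "model_II", "model_III",
                                           "constitutive_a", "constitutive_b",
                                           "mechanistic"),
                                kappa_mean = NULL, k_on = NULL, k_off = NULL,
                                kappa_tcf = NULL, env = NULL,
                                tau1 = NULL, tau2 = NULL, b = NULL, tau3 = 0) {
  family <- match.arg(family)
  need <- function(cond, what)
    if (!cond) stop(sprintf("family '%s' requires %s", family, what))
  reject <- function(x, what)
    if (!is.null(x)) stop(sprintf("family '%s' does not accept %s", family, what))
  obj <- list(family = family)
  if (family %in% c("model_I", "model_II", "model_III")) {
    need(is.numeric(kappa_mean) && kappa_mean > 0, "a positive kappa_mean (Hz)")
    obj$kappa_mean <- kappa_mean
    if (family == "model_I") {
      reject(k_on, "gene-switch rates"); reject(kappa_tcf, "a kappa TCF")
      obj$xi_tcf <- NULL; obj$kappa_tcf <- NULL
    } else {
      need(is.numeric(k_on) && is.numeric(k_off), "k_on and k_off (Hz)")
      obj$xi_tcf <- switching_tcf(k_on, k_off)
      if (family == "model_II") {
        reject(kappa_tcf, "a kappa TCF (that is the environment-coupled family)")
        obj$kappa_tcf <- NULL
      } else {
        need(inherits(kappa_tcf, "cft_tcf"), "a kappa_tcf (cft_tcf)")
        obj$kappa_tcf <- kappa_tcf
      }
    }
  } else if (family == "mechanistic") {
    need(is.numeric(tau1) && tau1 > 0, "positive tau1 (s)")
    need(is.numeric(tau2) && tau2 > 0, "positive tau2 (s)")
    need(is.numeric(b) && b > 0, "positive gamma dispersion b (s)")
    obj$tau1 <- tau1; obj$tau2 <- tau2; obj$b <- b; obj$tau3 <- tau3
    obj$waiting <- waiting_time("exp_gamma", tau1 = tau1, tau2 = tau2, b = b)
    obj$kappa_mean <- 1 / (tau1 + tau2)
    obj$xi_tcf <- NULL
    obj$kappa_tcf <- NULL   # computed on demand via renewal_rate_tcf(waiting)
  } else {
    need(inherits(env, "rnap_environment"), "an rnap_environment")
    need(is.numeric(kappa_mean) && kappa_mean > 0, "a positive mean k_TX (Hz)")
    if (family == "constitutive_b")
      need(!is.null(env$k_open) && !is.null(env$k_close),
           "dichotomous-affinity switch rates in the environment")
    obj$env <- env
    obj$kappa_mean <- kappa_mean
    obj$kappa_tcf <- kappa_tcf
  }
  structure(obj, class = "cft_model")
}

#' @export
print.cft_model <- function(x, ...) {
  cat("Transcription model:", x$family, "\n")
  if (!is.null(x$kappa_mean))
    cat(sprintf("  mean active-gene rate %.6g Hz\n", x$kappa_mean))
  if (!is.null(x$xi_tcf))
    cat(sprintf("  gene switching: k_on = %.4g, k_off = %.4g Hz (eta_xi^2 = %.4g)\n",
                x$xi_tcf$k_on, x$xi_tcf$k_off, x$xi_tcf$eta2))
  if (!is.null(x$kappa_tcf))
    cat(sprintf("  kappa TCF: %s, eta_kappa^2 = %.4g\n",
                x$kappa_tcf$kind, x$kappa_tcf$eta2))
  if (x$family == "mechanistic")
    cat(sprintf("  steps: tau1 = %.3g s, tau2 = %.3g s (b = %.3g s), tau3 = %.3g s\n",
                x$tau1, x$tau2, x$b, x$tau3))
  invisible(x)
}
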