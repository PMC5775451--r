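#' Copy-number mean, variance and the steady-state noise decomposition
#'
#' The central relation evaluated here expresses the variance of the mRNA
#' copy number as the mean plus a double time integral of the
#' transcription-rate covariance weighted by the mRNA survival probability:
#' \deqn{\sigma_n^2(t) = \langle n(t)\rangle + \int_0^t\!\!\int_0^t
#'   S(t-\tau_1) S(t-\tau_2)\,\langle\delta R(\tau_1)\delta R(\tau_2)\rangle
#'   \,d\tau_1 d\tau_2,}
#' with \eqn{\langle n(t)\rangle = \int_0^t \langle R(\tau)\rangle
#' S(t-\tau)\,d\tau}. In the stationary state, for a rate
#' \eqn{R = \xi\,\kappa} with independent factors, the relative variance
#' decomposes additively into a Poisson term and susceptibility-weighted
#' contributions of each factor's noise plus their bilinear coupling.
#'
#' @name cft_core
NULL

# overlap weight vector: A(u) = wvec . exp(T u) 1 with
# wvec derived from (alpha (x) alpha) (-(T (+) T))^{-1}; cached per lifetime.
ph_overlap_weights <- function(dist) {
  Tm <- dist$Tmat
  m <- nrow(Tm)
  M <- -(kronecker(Tm, diag(m)) + kronecker(diag(m), Tm))
  w <- solve(t(M), kronecker(dist$alpha, dist$alpha))  # row vec alpha2 M^-1
  rowSums(matrix(w, m, m))
}

#' Survival-overlap function of a lifetime model
#'
#' `A(u) = integral_0^Inf S(t) S(t+u) dt`, the lag-`u` overlap of the survival
#' probability with itself; the steady-state double integrals reduce to
#' one-dimensional integrals of `phi(u) A(u)`.
#'
#' @param dist a `cft_lifetime`.
#' @param u non-negative lags in seconds (vectorized).
#' @export
survival_overlap <- function(dist, u) {
  stopifnot(inherits(dist, "cft_lifetime"))
  if (any(u < 0)) stop("u must be non-negative")
  if (dist$kind == "delta") return(pmax(dist$tau - u, 0))
  wv <- ph_overlap_weights(dist)
  as.vector(wv %*% ph_expT_ones(dist, u))
}

#' Mean copy-number trajectory
#'
#' `mean_rate` may be a single number (constant mean transcription rate in Hz)
#' or a function of time.
#'
#' @param mean_rate mean transcription rate, Hz (number or function).
#' @param dist a `cft_lifetime`.
#' @param t times in seconds (vectorized).
#' @return mean copy numbers.
#' @export
mean_trajectory <- function(mean_rate, dist, t) {
  if (any(t < 0)) stop("t must be non-negative")
  rate <- if (is.function(mean_rate)) mean_rate else function(tt) rep(mean_rate, length(tt))
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(tau) rate(tau) * survival(dist, tt - tau),
                     0, tt, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 500L)$value
  }, 0)
}

#' Copy-number variance trajectory
#'
#' Evaluates the variance relation at finite time by two-dimensional
#' trapezoid quadrature on `[0, t]^2`. The rate covariance must be symmetric
#' in its two time arguments; this is checked on probe points.
#'
#' @param mean_rate mean transcription rate (number or function of time).
#' @param rate_cov covariance of the transcription-rate fluctuation:
#'   a function `(t1, t2)` in Hz^2, or `NULL` for a Poisson (constant-rate)
#'   process.
#' @param dist a `cft_lifetime`.
#' @param t time in seconds (scalar).
#' @param n quadrature nodes per axis.
#' @return list with `mean` and `variance` at `t`.
#' @export
variance_trajectory <- function(mean_rate, rate_cov, dist, t, n = 201) {
  stopifnot(length(t) == 1, t >= 0)
  mn <- mean_trajectory(mean_rate, dist, t)
  if (is.null(rate_cov)) return(list(mean = mn, variance = mn))
  probe <- t * c(0.12, 0.57)
  if (abs(rate_cov(probe[1], probe[2]) - rate_cov(probe[2], probe[1])) >
      1e-8 * (abs(rate_cov(probe[1], probe[2])) + 1e-300))
    stop("rate covariance is not symmetric in its arguments")
  tau <- seq(0, t, length.out = n)
  w <- rep(diff(tau)[1], n); w[c(1, n)] <- w[1] / 2
  s <- survival(dist, t - tau)
  C <- matrix(mapply(rate_cov, rep(tau, times = n), rep(tau, each = n)), n, n)
  integral <- as.numeric(t(w * s) %*% C %*% (w * s))
  list(mean = mn, variance = mn + integral)
}

# chi for a closed-form TCF given as complex-exponential terms
chi_terms_ph <- function(dist, terms) {
  wv <- ph_overlap_weights(dist)
  Tm <- dist$Tmat
  m <- nrow(Tm)
  tau_m <- mean_lifetime(dist)
  acc <- 0
  for (k in seq_len(nrow(terms))) {
    v <- solve(terms$z[k] * diag(m) - Tm, rep(1, m))
    acc <- acc + Re(terms$c[k] * sum(wv * v))
  }
  2 * acc / tau_m^2
}

chi_terms_delta <- function(tau, terms) {
  acc <- 0
  for (k in seq_len(nrow(terms))) {
    z <- terms$z[k]
    I <- if (abs(z) < 1e-14) tau^2 / 2 else (tau * z - 1 + exp(-z * tau)) / z^2
    acc <- acc + Re(terms$c[k] * I)
  }
  2 * acc / tau^2
}

#' Susceptibility of copy-number noise to a rate-factor TCF
#'
#' \deqn{\chi = \tau_m^{-2}\int_0^\infty\!\!\int_0^\infty S(t_1) S(t_2)
#'   \phi(|t_1-t_2|)\,dt_1 dt_2.}
#' Since the weights `S(t1)S(t2)/tau_m^2` integrate to 1 and `|phi| <= 1`,
#' `|chi| <= 1`, with `chi = 1` iff `phi` is identically 1 on the support of
#' `S`. Closed-form TCFs (sums of complex exponentials) are integrated
#' exactly via resolvent linear algebra; tabulated TCFs by trapezoid on their
#' lag grid. `method = "quadrature"` instead integrates
#' `phi(u) A(u)` by adaptive quadrature — an independent numerical route used
#' for cross-checks.
#'
#' @param dist a `cft_lifetime`.
#' @param tcf a `cft_tcf` (only its `phi` is used, not `eta2`).
#' @param method `"analytic"` (default) or `"quadrature"`.
#' @return dimensionless susceptibility.
#' @export
susceptibility <- function(dist, tcf, method = c("analytic", "quadrature")) {
  stopifnot(inherits(dist, "cft_lifetime"), inherits(tcf, "cft_tcf"))
  method <- match.arg(method)
  tau_m <- mean_lifetime(dist)
  if (method == "quadrature") {
    f <- function(u) tcf_phi(tcf, u) * survival_overlap(dist, u)
    upper <- if (!is.null(tcf$grid)) max(tcf$grid) else Inf
    val <- stats::integrate(f, 0, upper, rel.tol = 1e-11, abs.tol = 1e-14,
                            subdivisions = 1000L)$value
    return(2 * val / tau_m^2)
  }
  if (!is.null(tcf$terms)) {
    if (dist$kind == "delta") return(chi_terms_delta(dist$tau, tcf$terms))
    return(chi_terms_ph(dist, tcf$terms))
  }
  # tabulated TCF: trapezoid on its grid (phi vanishes beyond the grid)
  g <- tcf$grid
  integrand <- tcf$values * survival_overlap(dist, g)
  2 * trapz(g, integrand) / tau_m^2
}

#' @rdname susceptibility
#' @param tcf_kappa,tcf_xi the two factor TCFs; the bilinear susceptibility
#'   applies the susceptibility integral to the pointwise product
#'   `phi_kappa * phi_xi`.
#' @export
bilinear_susceptibility <- function(dist, tcf_kappa, tcf_xi,
                                    method = c("analytic", "quadrature")) {
  susceptibility(dist, product_tcf(tcf_kappa, tcf_xi), method = match.arg(method))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

new_noise <- function(mean_n, poisson_term, chi_xi = 0, chi_kappa = 0,
                      chi_bilinear = 0, term_xi = 0, term_kappa = 0,
                      term_bilinear = 0) {
  eta2 <- poisson_term + term_xi + term_kappa + term_bilinear
  structure(list(mean_n = mean_n, poisson_term = poisson_term,
                 chi_xi = chi_xi, chi_kappa = chi_kappa,
                 chi_bilinear = chi_bilinear,
                 term_xi = term_xi, term_kappa = term_kappa,
                 term_bilinear = term_bilinear,
                 eta2_n = eta2, fano = mean_n * eta2,
                 q_over_n = eta2 - poisson_term),
            class = "cft_noise")
}

#' Steady-state noise decomposition for a transcription model
#'
#' Evaluates the stationary relative variance of the single-copy mRNA number
#' as the additive decomposition
#' `1/<n>_1 + chi_kappa eta_kappa^2 + chi_xi eta_xi^2 +
#'  chi_bilinear eta_kappa^2 eta_xi^2`, with
#' `<n>_1 = <xi> <kappa> tau_m`. The constant-rate family has no fluctuation
#' terms; the telegraph family has only the gene-switching term; the
#' environment-coupled family adds the hidden-rate TCF and the bilinear
#' coupling.
#'
#' @param model a `cft_model` (see [transcription_model()]).
#' @param dist a `cft_lifetime`.
#' @param method susceptibility integration method.
#' @return a `cft_noise` with fields `mean_n`, the susceptibilities, the
#'   weighted terms, `eta2_n`, `fano` and `q_over_n`.
#' @export
steady_state_noise <- function(model, dist, method = "analytic") {
  stopifnot(inherits(model, "cft_model"), inherits(dist, "cft_lifetime"))
  tau_m <- mean_lifetime(dist)
  xi <- model$xi_tcf
  kap <- model$kappa_tcf
  xi_mean <- if (is.null(xi)) 1 else xi$xi_mean
  mean_n <- xi_mean * model$kappa_mean * tau_m
  chi_x <- chi_k <- chi_b <- t_x <- t_k <- t_b <- 0
  if (!is.null(xi) && xi$eta2 > 0) {
    chi_x <- susceptibility(dist, xi, method = method)
    t_x <- chi_x * xi$eta2
  }
  if (!is.null(kap) && kap$eta2 != 0) {
    chi_k <- susceptibility(dist, kap, method = method)
    t_k <- chi_k * kap$eta2
  }
  if (!is.null(xi) && xi$eta2 > 0 && !is.null(kap) && kap$eta2 != 0) {
    chi_b <- bilinear_susceptibility(dist, kap, xi, method = method)
    t_b <- chi_b * kap$eta2 * xi$eta2
  }
  new_noise(mean_n, 1 / mean_n, chi_xi = chi_x, chi_kappa = chi_k,
            chi_bilinear = chi_b, term_xi = t_x, term_kappa = t_k,
            term_bilinear = t_b)
}

#' @export
print.cft_noise <- function(x, ...) {
  cat("Steady-state mRNA noise decomposition\n")
  cat(sprintf("  mean <n>        %.6g\n", x$mean_n))
  cat(sprintf("  Poisson term    %.6g\n", x$poisson_term))
  if (x$term_xi != 0)
    cat(sprintf("  gene switching  %.6g (chi = %.4g)\n", x$term_xi, x$chi_xi))
  if (x$term_kappa != 0)
    cat(sprintf("  rate factor     %.6g (chi = %.4g)\n", x$term_kappa, x$chi_kappa))
  if (x$term_bilinear != 0)
    cat(sprintf("  bilinear        %.6g (chi = %.4g)\n", x$term_bilinear, x$chi_bilinear))
  cat(sprintf("  eta2_n = %.6g, Fano = %.6g, Q/<n> = %.6g\n",
              x$eta2_n, x$fano, x$q_over_n))
  invisible(x)
}
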