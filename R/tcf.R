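#' Time-correlation functions of transcription-rate factors
#'
#' A `cft_tcf` bundles the noise magnitude `eta2` = relative variance of a
#' stationary rate factor with its normalized correlation function
#' `phi(t)` (`phi(0) = 1`). Closed-form TCFs are stored as sums of complex
#' exponentials `phi(u) = Re sum_k c_k exp(-z_k u)`, which keeps products and
#' lifetime-weighted integrals exact; renewal-derived TCFs are tabulated on a
#' uniform lag grid. `eta2` is non-negative for genuine factor-noise TCFs;
#' renewal rate TCFs of sub-Poisson event streams carry a negative effective
#' `eta2` (their rate covariance is negative at short lags).
#'
#' @name cft_tcf
NULL

new_tcf <- function(eta2, terms = NULL, grid = NULL, values = NULL,
                    kind = "custom", extra = list()) {
  obj <- c(list(eta2 = eta2, terms = terms, grid = grid, values = values,
                kind = kind), extra)
  class(obj) <- "cft_tcf"
  obj
}

#' Evaluate the normalized correlation function of a TCF
#'
#' @param tcf a `cft_tcf`.
#' @param t lags in seconds (vectorized, non-negative).
#' @return `phi(t)`; tabulated TCFs are linearly interpolated and 0 beyond
#'   their grid.
#' @export
tcf_phi <- function(tcf, t) {
  stopifnot(inherits(tcf, "cft_tcf"))
  if (any(t < 0)) stop("lags must be non-negative")
  if (!is.null(tcf$terms)) {
    out <- rep(0, length(t))
    for (k in seq_len(nrow(tcf$terms)))
      out <- out + Re(tcf$terms$c[k] * exp(-tcf$terms$z[k] * t))
    return(out)
  }
  stats::approx(tcf$grid, tcf$values, xout = t, yleft = tcf$values[1],
                yright = 0, rule = 2, ties = "ordered")$y *
    ifelse(t > max(tcf$grid), 0, 1)
}

tcf_terms <- function(c, z) data.frame(c = complex(real = Re(c), imaginary = Im(c)),
                                       z = complex(real = Re(z), imaginary = Im(z)))

#' Gene-state switching (telegraph) TCF
#'
#' Two-state gene with activation rate `k_on` and inactivation rate `k_off`
#' (both Poisson). The active-state indicator has mean
#' `k_on / (k_on + k_off)`, relative variance `k_off / k_on`, and exponential
#' correlation decay at rate `k_on + k_off`.
#'
#' @param k_on activation rate in Hz (> 0).
#' @param k_off inactivation rate in Hz (>= 0).
#' @return a `cft_tcf` with an extra field `xi_mean`.
#' @export
switching_tcf <- function(k_on, k_off) {
  if (k_on <= 0) stop("k_on must be positive")
  if (k_off < 0) stop("k_off must be non-negative")
  new_tcf(eta2 = k_off / k_on,
          terms = tcf_terms(1, k_on + k_off),
          kind = "switching",
          extra = list(xi_mean = k_on / (k_on + k_off),
                       k_on = k_on, k_off = k_off))
}

#' Parametric environmental TCFs
#'
#' Closed-form families for the hidden-environment transcription-rate factor:
#' exponential decay `exp(-decay * t)` and damped cosine
#' `exp(-decay * t) * cos(freq * t)`; both are valid correlation functions for
#' any positive decay.
#'
#' @param kind `"exponential"` or `"damped_cosine"`.
#' @param eta2 relative variance of the factor (>= 0).
#' @param decay correlation decay rate in Hz (> 0).
#' @param freq angular frequency in rad/s (damped cosine only).
#' @export
parametric_env_tcf <- function(kind = c("exponential", "damped_cosine"),
                               eta2, decay, freq = NULL) {
  kind <- match.arg(kind)
  if (decay <= 0) stop("decay rate must be positive")
  if (eta2 < 0) stop("eta2 must be non-negative")
  terms <- if (kind == "exponential") {
    tcf_terms(1, decay)
  } else {
    if (is.null(freq) || freq <= 0) stop("damped_cosine requires a positive freq")
    tcf_terms(c(0.5, 0.5), complex(real = decay, imaginary = c(-freq, freq)))
  }
  new_tcf(eta2 = eta2, terms = terms, kind = kind)
}

#' Constant (infinitely slow) TCF
#'
#' `phi(t) = 1` for all lags: a static rate factor frozen per cell. Its
#' susceptibility is exactly 1 for any lifetime model.
#'
#' @param eta2 relative variance of the static factor.
#' @export
constant_tcf <- function(eta2 = 1) {
  if (eta2 < 0) stop("eta2 must be non-negative")
  new_tcf(eta2, terms = tcf_terms(1, 0), kind = "constant")
}

#' Pointwise product of two TCFs
#'
#' The TCF of the product of two independent factors has magnitude
#' `eta2_1 * eta2_2` and correlation `phi_1 * phi_2`; used for the bilinear
#' coupling term of the steady-state noise decomposition.
#'
#' @param a,b `cft_tcf` objects.
#' @export
product_tcf <- function(a, b) {
  stopifnot(inherits(a, "cft_tcf"), inherits(b, "cft_tcf"))
  if (!is.null(a$terms) && !is.null(b$terms)) {
    cc <- outer(a$terms$c, b$terms$c)
    zz <- outer(a$terms$z, b$terms$z, `+`)
    return(new_tcf(a$eta2 * b$eta2, terms = tcf_terms(as.vector(cc), as.vector(zz)),
                   kind = "product"))
  }
  # at least one tabulated: evaluate on the (finer) tabulated grid
  g <- if (!is.null(a$grid) && !is.null(b$grid)) {
    if (diff(a$grid[1:2]) <= diff(b$grid[1:2])) a$grid else b$grid
  } else if (!is.null(a$grid)) a$grid else b$grid
  new_tcf(a$eta2 * b$eta2, grid = g,
          values = tcf_phi(a, g) * tcf_phi(b, g), kind = "product")
}

#' Relative covariance of a composite transcription rate
#'
#' For a rate `R = xi * kappa` with independent factors, the stationary
#' relative covariance decomposes as
#' `eta_xi^2 phi_xi + eta_kappa^2 phi_kappa + eta_xi^2 eta_kappa^2 phi_xi phi_kappa`.
#' Returns an object whose components can be integrated term by term.
#'
#' @param tcf_xi,tcf_kappa `cft_tcf` objects for the two independent factors.
#' @return a `cft_ratecov`: list of `cft_tcf` components whose
#'   `eta2`-weighted `phi`s sum to the relative covariance of the rate.
#' @export
product_rate_tcf <- function(tcf_xi, tcf_kappa) {
  comps <- list()
  if (tcf_xi$eta2 != 0) comps <- c(comps, list(tcf_xi))
  if (tcf_kappa$eta2 != 0) comps <- c(comps, list(tcf_kappa))
  if (tcf_xi$eta2 != 0 && tcf_kappa$eta2 != 0)
    comps <- c(comps, list(product_tcf(tcf_xi, tcf_kappa)))
  structure(list(components = comps), class = "cft_ratecov")
}

#' Evaluate the relative rate covariance at given lags
#' @param rc a `cft_ratecov`.
#' @param t lags in seconds.
#' @export
rate_relcov <- function(rc, t) {
  stopifnot(inherits(rc, "cft_ratecov"))
  out <- rep(0, length(t))
  for (cmp in rc$components) out <- out + cmp$eta2 * tcf_phi(cmp, t)
  out
}

# ---- waiting-time distributions for renewal transcription -------------------

#' Transcription waiting-time distributions
#'
#' Waiting times between successive transcription initiations of an active
#' gene. Supported kinds: `"exponential"` (rate or mean), `"gamma"`
#' (mean and dispersion `b` = variance/mean, i.e. shape `mean/b`, scale `b`),
#' and `"exp_gamma"`, the convolution of an exponential initial-binding step
#' (mean `tau1`) with a gamma initiation step (mean `tau2`, dispersion `b`):
#' the promoter-occlusion model, where re-binding waits for the previous
#' polymerase to clear the promoter.
#'
#' @param kind distribution family.
#' @param mean mean waiting time in seconds (exponential/gamma).
#' @param b gamma dispersion parameter in seconds (variance/mean).
#' @param tau1,tau2 means of the two convolved steps (exp_gamma).
#' @return a `cft_waiting` with fields `mean`, `var` and a density.
#' @export
waiting_time <- function(kind = c("exponential", "gamma", "exp_gamma"),
                         mean = NULL, b = NULL, tau1 = NULL, tau2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (is.null(mean) || mean <= 0) stop("exponential waiting needs a positive mean")
    obj <- list(kind = kind, mean = mean, var = mean^2,
                dens = function(t) stats::dexp(t, 1 / mean))
  } else if (kind == "gamma") {
    if (is.null(mean) || is.null(b) || mean <= 0 || b <= 0)
      stop("gamma waiting needs positive mean and dispersion b")
    shape <- mean / b
    obj <- list(kind = kind, mean = mean, var = mean * b,
                dens = function(t) stats::dgamma(t, shape = shape, scale = b))
  } else {
    if (any(vapply(list(tau1, tau2, b), is.null, TRUE)))
      stop("exp_gamma waiting needs tau1, tau2 and b")
    if (tau1 <= 0 || tau2 <= 0 || b <= 0) stop("tau1, tau2, b must be positive")
    shape <- tau2 / b
    obj <- list(kind = kind, mean = tau1 + tau2, var = tau1^2 + tau2 * b,
                tau1 = tau1, tau2 = tau2, b = b,
                dens = local({
                  t1 <- tau1; sh <- shape; sc <- b
                  function(t) conv_exp_gamma(t, t1, sh, sc)
                }))
  }
  class(obj) <- "cft_waiting"
  obj
}

# density of Exp(1/tau1) + Gamma(shape, scale) by stable numeric quadrature
conv_exp_gamma <- function(t, tau1, shape, scale) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    f <- function(s) stats::dgamma(s, shape = shape, scale = scale) *
      stats::dexp(tt - s, 1 / tau1)
    stats::integrate(f, 0, tt, rel.tol = 1e-9, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value
  }, 0)
}

#' Renewal density of a stationary renewal point process
#'
#' Solves the renewal integral equation `h = psi + psi * h` (convolution) on a
#' uniform grid by trapezoid discretization, refined by two-grid Richardson
#' extrapolation. `h(t)` is the event-rate density a lag `t` after an event.
#'
#' @param waiting a `cft_waiting`.
#' @param tmax largest lag in seconds.
#' @param step grid step in seconds (default `mean/400`).
#' @return list with `grid` and `h`.
#' @export
renewal_density <- function(waiting, tmax, step = waiting$mean / 400) {
  stopifnot(inherits(waiting, "cft_waiting"))
  solve_one <- function(dt) {
    tt <- seq(0, tmax, by = dt)
    psi <- waiting$dens(tt)
    n <- length(tt)
    h <- numeric(n)
    h[1] <- psi[1]
    denom <- 1 - dt * psi[1] / 2
    for (i in 2:n) {
      s <- if (i > 2) sum(psi[2:(i - 1)] * h[(i - 1):2]) else 0
      h[i] <- (psi[i] + dt * (s + psi[i] * h[1] / 2)) / denom
    }
    list(grid = tt, h = h)
  }
  coarse <- solve_one(step)
  fine <- solve_one(step / 2)
  h <- (4 * fine$h[seq(1, length(fine$h), by = 2)] - coarse$h) / 3
  list(grid = coarse$grid, h = h)
}

#' Rate TCF of a renewal transcription process
#'
#' The stationary rate-fluctuation covariance of a renewal event stream,
#' excluding the same-event shot-noise delta (which is the Poisson term of the
#' copy-number variance relation): `cov(t) = r (h(t) - r)` for `t > 0`, with
#' `r = 1/mean` the stationary rate and `h` the renewal density. Returned in
#' `(eta2, phi)` form with `eta2 * r^2 * phi(t) = cov(t)` and `phi(0+) = 1`;
#' `eta2` is negative for sub-Poisson streams.
#'
#' @param waiting a `cft_waiting` with finite mean and variance.
#' @param tmax largest lag (default 8 mean waiting times; must cover >= 5).
#' @param step lag-grid step in seconds.
#' @export
renewal_rate_tcf <- function(waiting, tmax = 8 * waiting$mean,
                             step = waiting$mean / 400) {
  if (!is.finite(waiting$var))
    stop("waiting-time distributions with infinite variance are unsupported")
  if (tmax < 5 * waiting$mean)
    stop("lag grid must cover at least 5 mean waiting times")
  r <- 1 / waiting$mean
  rd <- renewal_density(waiting, tmax, step)
  covf <- r * (rd$h - r)
  if (max(abs(covf)) < 1e-12 * r^2)   # Poisson stream: no rate fluctuation
    return(new_tcf(0, grid = rd$grid, values = c(1, rep(0, length(rd$grid) - 1)),
                   kind = "renewal", extra = list(rate = r)))
  c0 <- covf[1]
  new_tcf(eta2 = c0 / r^2, grid = rd$grid, values = covf / c0,
          kind = "renewal", extra = list(rate = r))
}

#' @export
print.cft_tcf <- function(x, ...) {
  cat(sprintf("TCF (%s): eta2 = %.6g, %s\n", x$kind, x$eta2,
              if (!is.null(x$terms)) sprintf("%d closed-form term(s)", nrow(x$terms))
              else sprintf("tabulated on %d lags up to %.3g s",
                           length(x$grid), max(x$grid))))
  invisible(x)
}
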