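#' Cell-to-cell heterogeneity: the mixture (generalized) noise law
#'
#' When a model parameter — typically the mRNA degradation rate — differs
#' between cells, the population is a finite mixture of stationary per-cell
#' models and the pooled moments follow the law of total variance:
#' total mean `sum w_c <n>_c`, total variance
#' `sum w_c sigma_c^2 + sum w_c (<n>_c - <n>)^2`. This is the generalized
#' form of the variance relation for strongly heterogeneous lifetimes; the
#' continuous case is approximated by quadrature nodes.
#'
#' @name population
NULL

#' Heterogeneity model: weighted per-cell parameter overrides
#'
#' @param weights group weights (sum to 1).
#' @param overrides list (one element per group) of named lists; recognized
#'   entries: `dist` (a `cft_lifetime` replacing the base lifetime),
#'   `kappa_mean` (replacement mean rate, Hz), `rate_scale` (multiplier on
#'   the mean rate).
#' @export
heterogeneity_model <- function(weights, overrides) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("group weights must be non-negative and normalized")
  if (length(weights) != length(overrides))
    stop("one override set per group is required")
  structure(list(weights = weights, overrides = overrides),
            class = "cft_heterogeneity")
}

#' Steady-state noise of a heterogeneous cell population
#'
#' @param model base `cft_model`.
#' @param dist base `cft_lifetime`.
#' @param het a `cft_heterogeneity`.
#' @return a `cft_noise` with extra fields `within_var`, `between_var` and
#'   `groups` (per-group decompositions).
#' @export
heterogeneous_noise <- function(model, dist, het) {
  stopifnot(inherits(het, "cft_heterogeneity"))
  groups <- lapply(het$overrides, function(ov) {
    m <- model; d <- dist
    if (!is.null(ov$dist)) d <- ov$dist
    if (!is.null(ov$kappa_mean)) m$kappa_mean <- ov$kappa_mean
    if (!is.null(ov$rate_scale)) m$kappa_mean <- m$kappa_mean * ov$rate_scale
    steady_state_noise(m, d)
  })
  w <- het$weights
  means <- vapply(groups, function(x) x$mean_n, 0)
  vars <- vapply(groups, function(x) x$eta2_n * x$mean_n^2, 0)
  mean_n <- sum(w * means)
  within <- sum(w * vars)
  between <- sum(w * (means - mean_n)^2)
  v <- within + between
  out <- new_noise(mean_n, 1 / mean_n)
  out$eta2_n <- v / mean_n^2
  out$fano <- v / mean_n
  out$q_over_n <- out$eta2_n - 1 / mean_n
  out$within_var <- within
  out$between_var <- between
  out$groups <- groups
  out
}

# two-phase balanced-means fit of (tau_m, x): weights p and rates mu with
# pooled lifetime density p1 mu1 e^{-mu1 t} + p2 mu2 e^{-mu2 t}
h2_balanced <- function(tau_m, x) {
  if (x < 1) stop("attainable interval for this family is x >= 1 (requested x = ",
                  x, ")")
  if (abs(x - 1) < 1e-12) return(list(p = 1, mu = 1 / tau_m))
  p1 <- (1 + sqrt((x - 1) / (x + 1))) / 2
  list(p = c(p1, 1 - p1), mu = c(2 * p1 / tau_m, 2 * (1 - p1) / tau_m))
}

#' Lifetime-randomness dependence of non-Poisson mRNA noise
#'
#' `Delta(x)` is the change in single-copy non-Poisson noise `Q_n/<n>_1` as
#' the relative variance `x` of the mRNA lifetime moves away from the
#' exponential reference `x = 1`, at fixed mean lifetime `tau_m` and fixed
#' transcription model. Two model families realize the same bi-exponential
#' pooled lifetime distribution:
#' * `"homogeneous_super"` — every cell has the super-Poisson (hyperexponential)
#'   lifetime model; noise *decreases* with `x`;
#' * `"heterogeneous_rate"` — two cell groups, each with simple exponential
#'   degradation at its own rate; noise *increases* with `x`.
#'
#' @param family `"homogeneous_super"` or `"heterogeneous_rate"`.
#' @param model transcription `cft_model` held fixed along the family.
#' @param tau_m mean lifetime (s).
#' @param x relative variance of the lifetime (>= 1; `x = 1` gives 0).
#' @return `Delta(x)`, dimensionless.
#' @export
delta_measure <- function(family = c("homogeneous_super", "heterogeneous_rate"),
                          model, tau_m, x) {
  family <- match.arg(family)
  if (x <= 0) stop("x must be positive")
  q_ref <- steady_state_noise(model,
                              make_degradation_model("exponential",
                                                     gamma = 1 / tau_m))$q_over_n
  if (abs(x - 1) < 1e-12) return(0)
  fit <- h2_balanced(tau_m, x)
  q <- if (family == "homogeneous_super") {
    steady_state_noise(model, lifetime_hyperexponential(fit$p, fit$mu))$q_over_n
  } else {
    het <- heterogeneity_model(fit$p, lapply(fit$mu, function(mu)
      list(dist = make_degradation_model("exponential", gamma = mu))))
    heterogeneous_noise(model, NULL, het)$q_over_n
  }
  q - q_ref
}

#' Surface of Delta over a (tau_m, x) grid
#'
#' @inheritParams delta_measure
#' @param tau_grid mean lifetimes (s).
#' @param x_grid lifetime relative variances.
#' @return data frame with columns `tau_m`, `x`, `delta`.
#' @export
noise_surface <- function(family, model, tau_grid, x_grid) {
  grid <- expand.grid(tau_m = tau_grid, x = x_grid)
  grid$delta <- mapply(function(tm, xx) delta_measure(family, model, tm, xx),
                       grid$tau_m, grid$x)
  grid
}
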