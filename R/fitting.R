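#' Fitting transcription models to noise-versus-mean curves
#'
#' As an experimental control variable (repressor unbinding rate `k_off`, or
#' promoter affinity `K`) sweeps, the mean mRNA number per gene copy and the
#' non-Poisson noise `Q_n/<n>_1` trace a curve whose shape discriminates
#' between transcription models: constant-rate transcription gives a flat
#' curve at the copy-number offset, telegraph switching adds a mean-dependent
#' term, and an environment-coupled active-gene rate adds both a constant
#' term and a bilinear term that bends the curve. Fitting recovers the
#' hidden-TCF parameters (decay-rate ratio `lambda/gamma` and magnitude
#' `eta_kappa^2`).
#'
#' @name fitting
NULL

#' Default telegraph sweep family
#'
#' Fixed parameters of the noise-versus-mean forward model: mRNA decay rate
#' `gamma` (Hz), activation rate `k_on` (Hz), active-gene mean rate
#' `kappa_mean` (Hz), hidden-rate TCF decay ratio `lambda_ratio` =
#' `lambda/gamma` and magnitude `eta2_kappa`, plus the mean-independent
#' offset (copy-number Fano factor plus inter-copy correlation term).
#'
#' @param gamma mRNA decay rate (Hz).
#' @param k_on activation rate (Hz).
#' @param kappa_mean active-gene mean transcription rate (Hz).
#' @param lambda_ratio hidden-rate TCF decay over `gamma`.
#' @param eta2_kappa hidden-rate noise magnitude.
#' @param offset mean-independent non-Poisson noise floor.
#' @export
sweep_family <- function(gamma = 1/120, k_on = 0.01, kappa_mean = 1/12,
                         lambda_ratio = 306, eta2_kappa = 30, offset = 0.21) {
  list(gamma = gamma, k_on = k_on, kappa_mean = kappa_mean,
       lambda_ratio = lambda_ratio, eta2_kappa = eta2_kappa, offset = offset)
}

# closed-form single-copy q_over_n for exponential lifetime + exponential TCF;
# matches the resolvent path to rounding (asserted in tests)
q1_closed <- function(k_off, fam, family) {
  g <- fam$gamma; kon <- fam$k_on
  if (family == "model_I") return(rep(0, length(k_off)))
  eta_xi2 <- k_off / kon
  chi_xi <- g / (g + kon + k_off)
  q <- chi_xi * eta_xi2
  if (family == "model_III") {
    lam <- fam$lambda_ratio * g
    chi_k <- g / (g + lam)
    chi_b <- g / (g + lam + kon + k_off)
    q <- q + chi_k * fam$eta2_kappa + chi_b * fam$eta2_kappa * eta_xi2
  }
  q
}

#' Forward noise-versus-mean curve along a control sweep
#'
#' Evaluates, for each control value, the single-copy mean `mean_n1` and the
#' per-copy non-Poisson noise `q_over_n` = `Q_{n,1}/<n>_1` + offset. The
#' single-copy part goes through [steady_state_noise()]; the offset (copy
#' number + inter-copy correlation) is constant along the sweep.
#'
#' @param family `"model_I"`, `"model_II"` or `"model_III"`.
#' @param fam fixed parameters from [sweep_family()].
#' @param control which parameter sweeps (only `"k_off"` for these families).
#' @param grid control values (Hz).
#' @return data frame `control`, `mean_n1`, `q_over_n` (a noise curve).
#' @export
forward_curve <- function(family = c("model_III", "model_II", "model_I"),
                          fam = sweep_family(), control = "k_off", grid) {
  family <- match.arg(family)
  if (control != "k_off")
    stop("control '", control, "' is not applicable to the telegraph families")
  dist <- make_degradation_model("exponential", gamma = fam$gamma)
  ktcf <- if (family == "model_III")
    parametric_env_tcf("exponential", eta2 = fam$eta2_kappa,
                       decay = fam$lambda_ratio * fam$gamma)
  rows <- lapply(grid, function(koff) {
    if (family == "model_I") {
      # the control still sets the induction level (hence the mean), but
      # constant-rate transcription predicts no single-copy non-Poisson noise
      mean_n1 <- fam$k_on / (fam$k_on + koff) * fam$kappa_mean / fam$gamma
      return(c(mean_n1 = mean_n1, q_over_n = fam$offset))
    }
    m <- switch(family,
      model_II = transcription_model("model_II", kappa_mean = fam$kappa_mean,
                                     k_on = fam$k_on, k_off = koff),
      model_III = transcription_model("model_III", kappa_mean = fam$kappa_mean,
                                      k_on = fam$k_on, k_off = koff,
                                      kappa_tcf = ktcf))
    nd <- steady_state_noise(m, dist)
    c(mean_n1 = nd$mean_n, q_over_n = nd$q_over_n + fam$offset)
  })
  out <- data.frame(control = grid, do.call(rbind, rows))
  class(out) <- c("noise_curve", "data.frame")
  out
}

#' Generate a synthetic noise-curve fixture
#'
#' Applies seeded multiplicative lognormal noise (mean-preserving) of
#' relative size `noise` to the `q_over_n` column of a forward curve and
#' attaches the matching standard errors; optionally writes a TSV.
#'
#' @inheritParams forward_curve
#' @param noise relative noise level (e.g. 0.02 for 2\%).
#' @param seed integer seed; same seed reproduces the fixture bit for bit.
#' @param file optional TSV path.
#' @export
generate_noise_fixture <- function(family = "model_III", fam = sweep_family(),
                                   grid = 10^seq(-4, log10(2), length.out = 12),
                                   noise = 0.02, seed = 1, file = NULL) {
  curve <- forward_curve(family, fam, grid = grid)
  if (noise > 0) {
    set.seed(seed)
    s <- sqrt(log(1 + noise^2))
    curve$q_over_n <- curve$q_over_n *
      exp(stats::rnorm(nrow(curve), -s^2 / 2, s))
    curve$se <- noise * curve$q_over_n
  }
  if (!is.null(file))
    utils::write.table(curve, file, sep = "\t", quote = FALSE, row.names = FALSE)
  curve
}

#' Fit a transcription-model family to a noise curve
#'
#' Weighted least squares on `q_over_n` (weights `1/se^2` when a `se` column
#' is present, else uniform) with multi-start local optimization: starts are
#' drawn from a seeded Latin hypercube over the (log-scaled) parameter
#' bounds. Free parameters by family: `model_I` — `offset`;
#' `model_II` — `k_on`, `offset`; `model_III` — `k_on`, `lambda_ratio`,
#' `eta2_kappa`, `offset` (freeing `k_on` lets the richer families collapse
#' to a flat curve via fast switching when the data demand it).
#'
#' @param data a noise curve: data frame with columns `control`, `mean_n1`,
#'   `q_over_n` and optionally `se`.
#' @param family model family to fit.
#' @param fam fixed parameters ([sweep_family()]); free ones are overwritten.
#' @param lower,upper named bounds for the free parameters.
#' @param n_starts number of Latin-hypercube starts (>= 1).
#' @param seed seed for starts and bootstrap.
#' @param n_boot bootstrap resamples over rows for confidence intervals
#'   (0 to skip).
#' @return a `cft_fit` with `coefficients`, `rss`, `fitted`, `residuals`,
#'   `ci` (bootstrap 90\% intervals), `flat_warning` (identifiability flag)
#'   and the data.
#' @export
fit_noise_curve <- function(data, family = c("model_III", "model_II", "model_I"),
                            fam = sweep_family(),
                            lower = c(k_on = 1e-4, lambda_ratio = 1,
                                      eta2_kappa = 1e-3, offset = 0),
                            upper = c(k_on = 100, lambda_ratio = 1e4,
                                      eta2_kappa = 1e3, offset = 5),
                            n_starts = 16, seed = 1, n_boot = 100) {
  family <- match.arg(family)
  if (!all(c("control", "mean_n1", "q_over_n") %in% names(data)))
    stop("data must have columns control, mean_n1, q_over_n")
  if (max(data$mean_n1) <= 0 || diff(range(data$mean_n1)) == 0)
    stop("degenerate data: means do not vary along the sweep")
  free <- switch(family, model_I = "offset",
                 model_II = c("k_on", "offset"),
                 model_III = c("k_on", "lambda_ratio", "eta2_kappa", "offset"))
  if (nrow(data) < length(free) + 1)
    stop("need at least ", length(free) + 1, " rows for a ", length(free),
         "-parameter fit")
  w <- if ("se" %in% names(data)) 1 / data$se^2 else rep(1, nrow(data))
  # log scale for positive scale parameters; offset stays linear
  logp <- free[free != "offset"]
  to_int <- function(p) { p[logp] <- log(p[logp]); p }
  to_ext <- function(p) { p[logp] <- exp(p[logp]); p }
  obj <- function(pint) {
    p <- to_ext(pint)
    f <- fam; f[free] <- as.list(p[free])
    pred <- q1_closed(data$control, f, family) + f$offset
    sum(w * (data$q_over_n - pred)^2)
  }
  lo <- to_int(lower[free]); hi <- to_int(upper[free])
  set.seed(seed)
  starts <- matrix(lhs::randomLHS(n_starts, length(free)), n_starts)
  starts <- sweep(sweep(starts, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- free
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- tryCatch(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                               lower = lo, upper = hi,
                               control = list(factr = 10, maxit = 500,
                                              ndeps = rep(1e-6, length(free)))),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed to converge from every start")
  coefs <- to_ext(best$par)
  f <- fam; f[free] <- as.list(coefs[free])
  pred <- q1_closed(data$control, f, family) + f$offset
  # flat-direction detection: condition number of the weighted Jacobian normal
  # matrix at the optimum (finite differences on internal scale)
  J <- vapply(seq_along(free), function(j) {
    h <- 1e-5 * max(1, abs(best$par[j]))
    pp <- best$par; pp[j] <- pp[j] + h
    fj <- fam; fj[free] <- as.list(to_ext(pp)[free])
    (q1_closed(data$control, fj, family) + fj$offset - pred) / h
  }, numeric(nrow(data)))
  JtJ <- crossprod(sqrt(w) * J)
  kap <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  flat <- is.na(kap) || kap > 1e6 ||
    diff(range(log10(data$mean_n1))) < 1
  ci <- NULL
  if (n_boot > 0 && nrow(data) >= 4) {
    bs <- replicate(n_boot, {
      idx <- sample.int(nrow(data), replace = TRUE)
      db <- data[idx, ]; wb <- w[idx]
      ob <- function(pint) {
        p <- to_ext(pint)
        fb <- fam; fb[free] <- as.list(p[free])
        sum(wb * (db$q_over_n - q1_closed(db$control, fb, family) - fb$offset)^2)
      }
      ob2 <- tryCatch(stats::optim(best$par, ob, method = "L-BFGS-B",
                                   lower = lo, upper = hi,
                                   control = list(factr = 1e4))$par,
                      error = function(e) best$par)
      to_ext(ob2)
    })
    bs <- matrix(bs, nrow = length(free), dimnames = list(free, NULL))
    ci <- t(apply(bs, 1, stats::quantile, probs = c(0.05, 0.95)))
  }
  structure(list(coefficients = coefs, family = family, fam = f,
                 rss = best$value, fitted = pred,
                 residuals = data$q_over_n - pred,
                 data = data, weights = w, ci = ci,
                 flat_warning = flat, convergence = best$convergence),
            class = "cft_fit")
}

#' Fit and compare nested transcription-model families by RSS
#'
#' @inheritParams fit_noise_curve
#' @param families families to fit.
#' @return list of `cft_fit`s plus a comparison data frame `table`.
#' @export
compare_noise_models <- function(data, families = c("model_I", "model_II",
                                                    "model_III"),
                                 fam = sweep_family(), seed = 1, ...) {
  fits <- lapply(families, function(fm)
    fit_noise_curve(data, fm, fam = fam, seed = seed, n_boot = 0, ...))
  names(fits) <- families
  tab <- data.frame(family = families,
                    n_par = vapply(fits, function(f) length(f$coefficients), 0L),
                    rss = vapply(fits, function(f) f$rss, 0))
  list(fits = fits, table = tab,
       best = families[which.min(tab$rss)])
}

#' @export
print.cft_fit <- function(x, ...) {
  cat(sprintf("Noise-curve fit: %s (%d rows, RSS %.6g)\n",
              x$family, nrow(x$data), x$rss))
  print(round(x$coefficients, 6))
  if (x$flat_warning)
    cat("warning: flat direction detected (narrow mean range or ill-conditioned fit)\n")
  invisible(x)
}

#' @export
summary.cft_fit <- function(object, ...) {
  cat(sprintf("Family %s fitted to %d points by weighted least squares\n",
              object$family, nrow(object$data)))
  print(object$coefficients)
  if (!is.null(object$ci)) {
    cat("bootstrap 90% intervals:\n")
    print(object$ci)
  }
  cat(sprintf("RSS %.6g; residual sd %.4g\n", object$rss,
              stats::sd(object$residuals)))
  invisible(object)
}

#' @export
coef.cft_fit <- function(object, ...) object$coefficients

#' @export
predict.cft_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  q1_closed(d$control, object$fam, object$family) + object$fam$offset
}

#' @export
residuals.cft_fit <- function(object, ...) object$residuals

#' @export
plot.cft_fit <- function(x, ...) {
  ord <- order(x$data$mean_n1)
  graphics::plot(x$data$mean_n1[ord], x$data$q_over_n[ord], log = "x",
                 xlab = "mean mRNA per gene copy", ylab = "Q/<n>1",
                 main = paste("noise curve:", x$family), ...)
  graphics::lines(x$data$mean_n1[ord], x$fitted[ord], col = 2)
  invisible(x)
}
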