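#' Event-driven stochastic simulation of transcription and degradation
#'
#' Two engines, deliberately distinct:
#' * the *doubly stochastic* engine generates transcription events by a
#'   Poisson stream whose intensity `g * xi(t) * kappa(t)` is modulated by a
#'   two-state gene switch `xi` and a finite-state Markov rate modulator
#'   `kappa` — exactly the stochastic-intensity object the variance relation
#'   integrates;
#' * the *mechanistic* engine renews promoter cycles as exponential binding
#'   plus gamma initiation (promoter occlusion: no re-binding until initiation
#'   completes), the mRNA appearing a fixed elongation delay after each cycle;
#'   the gene is always active in this engine.
#'
#' Every mRNA receives an independent lifetime drawn by exact simulation of
#' the degradation chain. Random streams are derived per cell from
#' `(seed, cell index)`, so changing the number of cells does not reshuffle
#' existing cells.
#'
#' @name simulator
NULL

#' Finite-state Markov rate modulator realizing a target exponential TCF
#'
#' Two states with rates `(0, kappa_mean * (1 + eta2))`: occupancy of the high
#' state `1/(1 + eta2)` gives mean `kappa_mean`, relative variance `eta2`, and
#' exponential correlation decay at rate `decay`, for any `eta2 > 0`.
#'
#' @param kappa_mean mean rate in Hz.
#' @param eta2 relative variance of the modulated rate (> 0).
#' @param decay TCF decay rate in Hz.
#' @return modulator spec used by [cell_config()].
#' @export
kappa_modulator_exponential <- function(kappa_mean, eta2, decay) {
  stopifnot(kappa_mean > 0, eta2 > 0, decay > 0)
  p_high <- 1 / (1 + eta2)
  list(kind = "markov",
       values = c(0, kappa_mean / p_high),
       Q = matrix(c(-decay * p_high, decay * p_high,
                    decay * (1 - p_high), -decay * (1 - p_high)),
                  2, 2, byrow = TRUE),
       stationary = c(1 - p_high, p_high))
}

#' Constant-rate modulator
#' @param kappa rate in Hz.
#' @export
kappa_modulator_constant <- function(kappa) {
  list(kind = "constant", values = kappa, Q = NULL, stationary = 1)
}

#' Simulation cell configuration
#'
#' @param engine `"doubly_stochastic"` or `"mechanistic"`.
#' @param k_on,k_off gene-switch rates in Hz (`NULL` for an always-active
#'   gene).
#' @param kappa modulator spec (doubly stochastic engine), e.g. from
#'   [kappa_modulator_exponential()] or [kappa_modulator_constant()].
#' @param tau1,tau2,b,tau3 mechanistic step parameters (seconds).
#' @param degradation a `cft_lifetime`.
#' @param g gene copies driven by the shared intensity (integer >= 0).
#' @param horizon simulated time per cell in seconds (counts taken here).
#' @param burn_in portion of the horizon discarded from event logs (s).
#' @export
cell_config <- function(engine = c("doubly_stochastic", "mechanistic"),
                        k_on = NULL, k_off = NULL,
                        kappa = NULL,
                        tau1 = NULL, tau2 = NULL, b = NULL, tau3 = 0,
                        degradation, g = 1L, horizon, burn_in = 0) {
  engine <- match.arg(engine)
  stopifnot(inherits(degradation, "cft_lifetime"))
  if (horizon <= burn_in || burn_in < 0)
    stop("need horizon > burn_in >= 0")
  if (g < 0) stop("g must be >= 0")
  if (engine == "doubly_stochastic") {
    if (is.null(kappa)) stop("doubly stochastic engine needs a kappa modulator")
    if (any(!is.finite(kappa$values)))
      stop("unbounded kappa modulator is unsupported")
  } else {
    if (is.null(tau1) || is.null(tau2) || is.null(b) || tau1 <= 0 || tau2 <= 0)
      stop("mechanistic engine needs positive tau1, tau2 (and dispersion b)")
  }
  structure(list(engine = engine, k_on = k_on, k_off = k_off, kappa = kappa,
                 tau1 = tau1, tau2 = tau2, b = b, tau3 = tau3,
                 degradation = degradation, g = as.integer(g),
                 horizon = horizon, burn_in = burn_in),
            class = "cft_cell_config")
}

# per-cell seeds: scrambled through R's RNG so that arithmetic structure in
# (seed, cell index) cannot induce cross-cell stream correlation; drawing
# without replacement keeps the prefix stable when n_cells grows
cell_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# piecewise-constant intensity stream for one cell; returns birth times in [0, H]
sim_intensity_stream <- function(cfg, scale) {
  H <- cfg$horizon
  # joint modulator: xi (optional telegraph) x kappa (markov or constant)
  has_xi <- !is.null(cfg$k_on)
  if (has_xi) {
    p_on <- cfg$k_on / (cfg$k_on + cfg$k_off)
    xi <- stats::rbinom(1, 1, p_on)
  } else xi <- 1L
  kap <- cfg$kappa
  ks <- if (kap$kind == "constant") 1L
        else sample.int(length(kap$stationary), 1, prob = kap$stationary)
  t <- 0
  births <- vector("list", 64); nb <- 0
  while (t < H) {
    rate_xi <- if (has_xi) { if (xi == 1L) cfg$k_off else cfg$k_on } else 0
    rate_k <- if (is.null(kap$Q)) 0 else -kap$Q[ks, ks]
    qtot <- rate_xi + rate_k
    dt <- if (qtot > 0) stats::rexp(1, qtot) else H - t
    seg_end <- min(t + dt, H)
    intensity <- cfg$g * scale * xi * kap$values[ks]
    if (intensity > 0 && seg_end > t) {
      nB <- stats::rpois(1, intensity * (seg_end - t))
      if (nB > 0) {
        nb <- nb + 1
        if (nb > length(births)) births <- c(births, vector("list", length(births)))
        births[[nb]] <- t + sort(stats::runif(nB, 0, seg_end - t))
      }
    }
    t <- seg_end
    if (t < H && qtot > 0) {
      if (stats::runif(1) < rate_xi / qtot) {
        xi <- 1L - xi
      } else {
        p <- kap$Q[ks, ]; p[ks] <- 0
        ks <- sample.int(length(p), 1, prob = p)
      }
    }
  }
  if (nb == 0) numeric(0) else unlist(births[seq_len(nb)], use.names = FALSE)
}

#' Simulate cells with a doubly stochastic transcription intensity
#'
#' @param cfg a [cell_config()] with engine `"doubly_stochastic"`.
#' @param n_cells number of cells.
#' @param seed master seed (integer); per-cell streams are derived from it.
#' @param rate_scale per-cell multiplicative factor on the intensity (length 1
#'   or `n_cells`); used e.g. for a static per-cell polymerase environment.
#' @param log_events keep per-cell transcription event times (after burn-in)?
#' @return a `cft_sim` with `counts` (mRNA per cell at the horizon), optional
#'   `events`, and the realized configuration.
#' @export
simulate_doubly_stochastic <- function(cfg, n_cells, seed = 1,
                                       rate_scale = 1, log_events = FALSE) {
  stopifnot(inherits(cfg, "cft_cell_config"), cfg$engine == "doubly_stochastic")
  rate_scale <- rep_len(rate_scale, n_cells)
  counts <- integer(n_cells)
  events <- if (log_events) vector("list", n_cells) else NULL
  H <- cfg$horizon
  seeds <- cell_seeds(seed, n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    b <- sim_intensity_stream(cfg, rate_scale[i])
    if (length(b)) {
      life <- sample_lifetimes(cfg$degradation, length(b))
      counts[i] <- sum(b + life > H)
    }
    if (log_events) events[[i]] <- b[b >= cfg$burn_in]
  }
  structure(list(counts = counts, events = events, cfg = cfg, seed = seed,
                 span = H - cfg$burn_in),
            class = "cft_sim")
}

#' Simulate the mechanistic renewal transcription engine
#'
#' Promoter cycles are drawn as exponential(tau1) + gamma(mean tau2,
#' dispersion b) waits; the mRNA appears `tau3` seconds after each cycle
#' completes (elongation is non-blocking). The gene is always active.
#'
#' @inheritParams simulate_doubly_stochastic
#' @param cfg a [cell_config()] with engine `"mechanistic"`.
#' @export
simulate_mechanistic <- function(cfg, n_cells, seed = 1, log_events = FALSE) {
  stopifnot(inherits(cfg, "cft_cell_config"), cfg$engine == "mechanistic")
  counts <- integer(n_cells)
  events <- if (log_events) vector("list", n_cells) else NULL
  H <- cfg$horizon
  mean_w <- cfg$tau1 + cfg$tau2
  shape <- cfg$tau2 / cfg$b
  seeds <- cell_seeds(seed, n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    b <- numeric(0); t_end <- 0
    repeat {
      n_blk <- max(16L, ceiling((H - t_end) / mean_w * 1.15))
      w <- stats::rexp(n_blk, 1 / cfg$tau1) +
        stats::rgamma(n_blk, shape = shape, scale = cfg$b)
      b <- c(b, t_end + cumsum(w))
      t_end <- b[length(b)]
      if (t_end >= H) break
    }
    b <- b[b <= H - cfg$tau3] + cfg$tau3
    if (length(b)) {
      life <- sample_lifetimes(cfg$degradation, length(b))
      counts[i] <- sum(b + life > H)
    }
    if (log_events) events[[i]] <- b[b >= cfg$burn_in]
  }
  structure(list(counts = counts, events = events, cfg = cfg, seed = seed,
                 span = H - cfg$burn_in),
            class = "cft_sim")
}

#' Moment estimates with bootstrap standard errors
#'
#' Plug-in mean, variance, Fano factor and non-Poisson noise of per-cell
#' counts, with standard errors from bootstrap resampling over cells.
#'
#' @param x a `cft_sim` or a numeric vector of per-cell counts.
#' @param n_boot bootstrap resamples (>= 200 recommended).
#' @param seed seed for the bootstrap.
#' @return list with `mean`, `var`, `fano`, `q_over_n` and `se` (named vector
#'   of bootstrap standard errors).
#' @export
estimate_noise <- function(x, n_boot = 200, seed = 1) {
  counts <- if (inherits(x, "cft_sim")) x$counts else x
  n <- length(counts)
  if (n < 2) stop("need at least 2 cells to estimate noise")
  stat <- function(v) {
    m <- mean(v); s2 <- stats::var(v)
    c(mean = m, var = s2, fano = s2 / m, q_over_n = s2 / m^2 - 1 / m)
  }
  est <- stat(counts)
  set.seed(seed)
  bs <- replicate(n_boot, stat(counts[sample.int(n, n, replace = TRUE)]))
  list(mean = est[["mean"]], var = est[["var"]], fano = est[["fano"]],
       q_over_n = est[["q_over_n"]],
       se = apply(bs, 1, stats::sd))
}

#' Estimate the transcription-rate TCF from simulated event streams
#'
#' Computes the binned-rate autocovariance of the event stream with the
#' same-event shot-noise removed, i.e. the estimator of
#' `cov(u) = r (h(u) - r)` with `h` the renewal density, via the pair-lag
#' histogram (equivalent to the binned-count autocovariance, but linear in
#' the number of event pairs). Normalization follows the analytic convention:
#' `phi(0+) = 1`, `eta2 * r^2 * phi = cov`.
#'
#' @param sim a `cft_sim` simulated with `log_events = TRUE`, or a list of
#'   per-cell event-time vectors plus attribute-free `span` argument.
#' @param bin_width lag bin width in seconds.
#' @param max_lag largest lag in seconds (multiple of `bin_width`).
#' @param span observation span per cell (seconds); taken from the `cft_sim`
#'   when available.
#' @return a `cft_tcf_estimate`: list with bin-center `grid`, `cov`, `phi`,
#'   `eta2`, `rate`, and per-cell pair counts for bootstrap use.
#' @export
estimate_rate_tcf <- function(sim, bin_width, max_lag, span = NULL) {
  events <- if (inherits(sim, "cft_sim")) sim$events else sim
  if (is.null(events) || !length(events) || !sum(lengths(events)))
    stop("no logged events: simulate with log_events = TRUE")
  if (inherits(sim, "cft_sim")) span <- sim$span
  if (is.null(span)) stop("span (observation time per cell) is required")
  nbin <- round(max_lag / bin_width)
  if (abs(nbin * bin_width - max_lag) > 1e-9)
    stop("max_lag must be a multiple of bin_width")
  P <- matrix(0, length(events), nbin)
  for (ci in seq_along(events)) {
    t <- events[[ci]]
    n <- length(t)
    if (n < 2) next
    d <- 1L
    repeat {
      if (d >= n) break
      diffs <- t[(1 + d):n] - t[1:(n - d)]
      diffs <- diffs[diffs <= max_lag]
      if (!length(diffs)) break
      idx <- pmax(1L, ceiling(diffs / bin_width))
      P[ci, ] <- P[ci, ] + tabulate(idx, nbins = nbin)
      d <- d + 1L
    }
  }
  ncell <- lengths(events)
  grid <- (seq_len(nbin) - 0.5) * bin_width
  est <- function(rows) {
    ntot <- sum(ncell[rows]); Ltot <- sum(rep(span, length(rows)))
    r <- ntot / Ltot
    # pairs expected per bin for a Poisson stream: ntot * r * w * (1 - u/L)
    h <- colSums(P[rows, , drop = FALSE]) / (ntot * bin_width * (1 - grid / span))
    r * (h - r)
  }
  cov <- est(seq_along(events))
  r <- sum(ncell) / (span * length(events))
  structure(list(grid = grid, cov = cov, phi = cov / cov[1],
                 eta2 = cov[1] / r^2, rate = r,
                 pair_counts = P, events_per_cell = ncell, span = span,
                 bin_width = bin_width, est_fun = est),
            class = "cft_tcf_estimate")
}

#' Bootstrap standard errors for an estimated rate-TCF covariance
#'
#' @param est a `cft_tcf_estimate`.
#' @param n_boot bootstrap resamples over cells.
#' @param seed seed.
#' @return matrix-free list with `se` (per-lag SE of the covariance).
#' @export
tcf_estimate_se <- function(est, n_boot = 200, seed = 1) {
  ncell <- nrow(est$pair_counts)
  if (ncell < 2) stop("bootstrap needs >= 2 cells")
  set.seed(seed)
  bs <- replicate(n_boot, est$est_fun(sample.int(ncell, ncell, replace = TRUE)))
  list(se = apply(bs, 1, stats::sd))
}

#' Locate local maxima of a tabulated correlation/covariance curve
#'
#' A lag is reported as a peak when it carries the maximum value within a
#' centered window of half-width `half_window` and exceeds `level`. Used to
#' measure oscillation periods of renewal rate TCFs.
#'
#' @param grid lags (s).
#' @param values curve values.
#' @param half_window half-width of the locality window (s).
#' @param level minimum value for a peak (default 0).
#' @return vector of peak lags, increasing.
#' @export
find_peak_lags <- function(grid, values, half_window, level = 0) {
  peaks <- numeric(0)
  for (i in seq_along(grid)) {
    win <- abs(grid - grid[i]) <= half_window
    if (values[i] > level && values[i] >= max(values[win]) &&
        grid[i] > half_window && grid[i] < max(grid) - half_window) {
      if (!length(peaks) || grid[i] - peaks[length(peaks)] > half_window)
        peaks <- c(peaks, grid[i])
    }
  }
  peaks
}

#' @export
print.cft_sim <- function(x, ...) {
  cat(sprintf("Simulation: %d cells, engine %s, horizon %.4g s\n",
              length(x$counts), x$cfg$engine, x$cfg$horizon))
  cat(sprintf("  mean count %.4g, variance %.4g\n",
              mean(x$counts), stats::var(x$counts)))
  invisible(x)
}
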