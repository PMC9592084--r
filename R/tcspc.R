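# TCSPC histogram simulation and lifetime fitting.
#
# The observed photon-arrival density for a fluorophore excited by a periodic
# pulse train (period T) and detected through a Gaussian instrument response
# (IRF) is a periodically wrapped exponentially-modified Gaussian (EMG): each
# excitation pulse contributes the closed-form exponential (x) Gaussian
# convolution, and the arrival time is observed modulo T, so every bin
# inherits the residue of all previous pulses.  Bin probabilities are exact
# differences of the EMG CDF summed over pulse shifts, evaluated in log space
# for numerical stability.

#' Gaussian instrument-response model
#'
#' @param center_time Offset of the IRF peak within the laser period (ns).
#' @param width_sigma Gaussian standard deviation of the IRF (ns, > 0).
#' @param laser_period Laser period the offset must fall in (ns), used only
#'   for validation.
#' @return An object of class `irf_model`.
#' @export
irf_model <- function(center_time = 1.5, width_sigma = 0.2, laser_period = 12.5) {
  out <- list(
    center_time = check_scalar(center_time, "center_time", lower = 0,
                               upper = laser_period, strict_upper = TRUE),
    width_sigma = check_scalar(width_sigma, "width_sigma", lower = 0,
                               strict_lower = TRUE)
  )
  class(out) <- "irf_model"
  out
}

#' Periodic (bi)exponential decay model
#'
#' @param components Two-column description of decay components: a list
#'   of `c(amplitude_fraction, lifetime_tau_ns)` pairs, or a numeric matrix
#'   with columns amplitude and lifetime.  Amplitude fractions must be > 0 and
#'   sum to 1; lifetimes must be > 0.
#' @param background_fraction Fraction of photons arriving uniformly over the
#'   period (dark counts / ambient light), in `[0, 1)`.
#' @param laser_period Laser repetition period (ns); 12.5 ns for an 80 MHz
#'   Ti:Sapphire source.
#' @return An object of class `decay_model`.
#' @export
#' @examples
#' decay_model(list(c(0.7, 0.4), c(0.3, 4.5)))  # Peredox-like, tau8 = 1.63 ns
decay_model <- function(components, background_fraction = 0, laser_period = 12.5) {
  if (is.list(components)) components <- do.call(rbind, components)
  components <- as.matrix(components)
  if (ncol(components) != 2L || nrow(components) < 1L)
    stop_invalid("`components` must be (amplitude, lifetime) pairs")
  amps <- components[, 1]
  taus <- components[, 2]
  if (any(!is.finite(amps)) || any(amps <= 0))
    stop_invalid("amplitude fractions must be finite and > 0")
  if (abs(sum(amps) - 1) > 1e-8)
    stop_invalid("amplitude fractions must sum to 1 (got %g)", sum(amps))
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop_invalid("lifetimes must be finite and > 0")
  out <- list(
    amplitudes = as.numeric(amps / sum(amps)),
    lifetimes = as.numeric(taus),
    background_fraction = check_scalar(background_fraction, "background_fraction",
                                       lower = 0, upper = 1, strict_upper = TRUE),
    laser_period = check_scalar(laser_period, "laser_period", lower = 0,
                                strict_lower = TRUE)
  )
  class(out) <- "decay_model"
  out
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("Decay model (period %g ns, background %.3g):\n",
              x$laser_period, x$background_fraction))
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  a = %.4f  tau = %.4f ns\n", x$amplitudes[i], x$lifetimes[i]))
  invisible(x)
}

#' TCSPC photon-arrival histogram
#'
#' @param bin_edges Uniform, strictly increasing bin edges spanning exactly
#'   one laser period (ns); length `n_bins + 1`.
#' @param counts Non-negative integer photon counts per bin.
#' @param channel Detection channel label, `"green"` or `"red"`.
#' @return An object of class `tcspc_histogram` with fields `bin_edges`,
#'   `counts`, `channel`, `total_photons`, `laser_period`.
#' @export
tcspc_histogram <- function(bin_edges, counts, channel = c("green", "red")) {
  channel <- match.arg(channel)
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || !is_uniform_grid(bin_edges))
    stop_invalid("`bin_edges` must be uniform and strictly increasing")
  if (length(counts) != length(bin_edges) - 1L)
    stop_invalid("`counts` must have length(bin_edges) - 1 entries")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop_invalid("`counts` must be non-negative integers")
  counts <- as.numeric(round(counts))
  out <- list(bin_edges = bin_edges, counts = counts, channel = channel,
              total_photons = sum(counts),
              laser_period = bin_edges[length(bin_edges)] - bin_edges[1])
  class(out) <- "tcspc_histogram"
  out
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("TCSPC histogram (%s): %d bins over %g ns, %g photons\n",
              x$channel, length(x$counts), x$laser_period, x$total_photons))
  invisible(x)
}

# CDF of the exponentially-modified Gaussian (decay rate lam = 1/tau, IRF
# centre mu, width sigma), stable in log space.  Vectorised over x.
emg_cdf <- function(x, mu, sigma, lam) {
  if (sigma < 1e-12) {
    d <- x - mu
    return(ifelse(d > 0, 1 - exp(-lam * d), 0))
  }
  u <- (x - mu) / sigma
  lg <- -lam * (x - mu) + 0.5 * (lam * sigma)^2 +
    pnorm(u - lam * sigma, log.p = TRUE)
  val <- pnorm(u) - exp(lg)
  pmin(pmax(val, 0), 1)
}

# Per-bin probabilities of a single periodically wrapped EMG component.
# Pulses near the observation window use the exact EMG CDF; once all bin
# edges sit far past the Gaussian (x > mu + 10 sigma) the EMG pdf is a pure
# exponential and the remaining infinite pulse sum collapses to a geometric
# factor.
wrapped_emg_bin_probs <- function(tau, mu, sigma, bin_edges, period) {
  lam <- 1 / tau
  # smallest shift after which every edge clears the Gaussian region
  j_exact <- max(1L, ceiling((mu + 10 * sigma - bin_edges[1]) / period))
  shifts <- seq.int(-2L, j_exact) * period
  edge_mat <- outer(bin_edges, shifts, `+`)
  cdf <- emg_cdf(edge_mat, mu, sigma, lam)
  p <- rowSums(cdf[-1L, , drop = FALSE] - cdf[-nrow(cdf), , drop = FALSE])
  # analytic tail: sum_{j > j_exact} of exp-only contributions
  r <- exp(-lam * period)
  if (r > 0) {
    e <- exp(-lam * (bin_edges - mu + (j_exact + 1L) * period) +
               0.5 * (lam * sigma)^2)
    p <- p + (e[-length(e)] - e[-1L]) * 1 / (1 - r)
  }
  p <- pmax(p, 0)
  p / sum(p)
}

#' Expected TCSPC bin probabilities for a decay model
#'
#' Exact per-bin probabilities of the periodic exponential-decay model
#' convolved with a Gaussian IRF, with wrap-around of the exponential tail
#' across laser periods and a uniform background term.  Probabilities sum to
#' one over the period.
#'
#' @param model A [decay_model()].
#' @param irf An [irf_model()].
#' @param bin_edges Uniform bin edges spanning exactly one laser period (ns).
#' @return Numeric vector of per-bin probabilities (length
#'   `length(bin_edges) - 1`), summing to 1.
#' @export
#' @examples
#' m <- decay_model(list(c(1, 2.0)))
#' p <- expected_decay_curve(m, irf_model(1.0, 0.1), seq(0, 12.5, length.out = 257))
#' sum(p)  # 1
expected_decay_curve <- function(model, irf, bin_edges) {
  stopifnot(inherits(model, "decay_model"), inherits(irf, "irf_model"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || !is_uniform_grid(bin_edges))
    stop_invalid("`bin_edges` must be uniform and strictly increasing")
  span <- bin_edges[length(bin_edges)] - bin_edges[1]
  if (abs(span - model$laser_period) > 1e-6 * model$laser_period)
    stop_invalid("bin edges span %g ns but the laser period is %g ns",
                 span, model$laser_period)
  if (any(model$lifetimes >= 100 * model$laser_period))
    warning("lifetime >= 100 laser periods: decay is nearly flat over the ",
            "period and the fit is ill-conditioned", call. = FALSE)
  nb <- length(bin_edges) - 1L
  p <- numeric(nb)
  if (model$background_fraction < 1) {
    for (i in seq_along(model$lifetimes)) {
      p <- p + model$amplitudes[i] *
        wrapped_emg_bin_probs(model$lifetimes[i], irf$center_time,
                              irf$width_sigma, bin_edges, model$laser_period)
    }
  }
  p <- (1 - model$background_fraction) * p + model$background_fraction / nb
  p / sum(p)
}

#' Simulate a TCSPC histogram
#'
#' Draws a multinomial photon realisation of [expected_decay_curve()],
#' reproducibly for a fixed seed.  The caller's RNG state is untouched.
#'
#' @inheritParams expected_decay_curve
#' @param n_photons Total photons to distribute (>= 1).
#' @param n_bins Number of uniform bins over the period (>= 16; default 256).
#' @param seed Integer seed.
#' @param channel Channel label for the resulting histogram.
#' @return A [tcspc_histogram()].
#' @export
simulate_histogram <- function(model, irf, n_photons, n_bins = 256L, seed = 1L,
                               channel = "green") {
  stopifnot(inherits(model, "decay_model"))
  n_photons <- check_scalar(n_photons, "n_photons", lower = 1)
  n_bins <- as.integer(check_scalar(n_bins, "n_bins", lower = 16))
  edges <- seq(0, model$laser_period, length.out = n_bins + 1L)
  p <- expected_decay_curve(model, irf, edges)
  counts <- with_seed(seed, as.vector(rmultinom(1L, size = n_photons, prob = p)))
  tcspc_histogram(edges, counts, channel = channel)
}

# Parameter packing for the fit: lifetimes on log scale, amplitude of the
# first component through a logistic, background through a logistic, optional
# IRF centre (raw) and width (log).
pack_theta <- function(taus, a1, bg, irf, fit_bg, fit_irf) {
  th <- log(taus)
  if (length(taus) == 2L) th <- c(th, stats::qlogis(min(max(a1, 1e-6), 1 - 1e-6)))
  if (fit_bg) th <- c(th, stats::qlogis(min(max(bg, 1e-9), 0.5)))
  if (fit_irf) th <- c(th, irf$center_time, log(irf$width_sigma))
  th
}

unpack_theta <- function(th, n_components, fit_bg, fit_irf, irf0, period) {
  i <- n_components
  taus <- exp(th[seq_len(i)])
  if (n_components == 2L) {
    a1 <- stats::plogis(th[i + 1L]); i <- i + 1L
    amps <- c(a1, 1 - a1)
  } else amps <- 1
  bg <- 0
  if (fit_bg) { bg <- stats::plogis(th[i + 1L]); i <- i + 1L }
  irf <- irf0
  if (fit_irf) {
    ct <- th[i + 1L] %% period
    sg <- exp(th[i + 2L])
    irf <- irf_model(ct, max(sg, 1e-4), laser_period = period)
  }
  list(amps = amps, taus = taus, bg = bg, irf = irf)
}

#' Fit a lifetime decay model to a TCSPC histogram
#'
#' Nonlinear fit of [expected_decay_curve()] to the observed counts,
#' restricted to the window from the peak-count bin (earliest bin at the
#' maximum) to `window_after_peak` ns after it — the "tau8" windowing when
#' `window_after_peak = 8`.  The default objective is the Poisson negative
#' log-likelihood with the overall scale profiled out; Pearson-weighted least
#' squares is available via `objective = "leastsq"`.
#'
#' @param hist A [tcspc_histogram()] with at least 100 photons.
#' @param irf An [irf_model()] with known parameters, or `NULL` to co-fit the
#'   IRF (initialised at the peak bin with sigma 0.2 ns).
#' @param n_components 1 or 2 exponential components.
#' @param window_after_peak Fit-window length after the peak bin (ns,
#'   default 8), or `NULL` to fit every bin of the period.
#' @param objective `"poisson"` (maximum likelihood, default) or `"leastsq"`.
#' @param fit_background Fit a uniform background fraction (default TRUE).
#' @param control List of optimiser controls: `reltol` (default 1e-8),
#'   `maxit` (default 500).
#' @return An object of class `lifetime_fit` with fields `fitted_components`
#'   (amplitude/lifetime matrix, lifetimes ascending), `fitted_irf`,
#'   `fitted_background`, `tau8` (amplitude-weighted mean lifetime),
#'   `fit_window`, `goodness` (reduced Pearson chi-square), `converged`,
#'   `objective`, `n_photons_in_window`.
#' @export
fit_lifetime <- function(hist, irf = NULL, n_components = 2L,
                         window_after_peak = 8,
                         objective = c("poisson", "leastsq"),
                         fit_background = TRUE, control = list()) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  objective <- match.arg(objective)
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L))
    stop_invalid("`n_components` must be 1 or 2")
  if (hist$total_photons < 100)
    stop_invalid("histogram has %g photons; at least 100 are required",
                 hist$total_photons)
  period <- hist$laser_period
  if (!is.null(window_after_peak))
    window_after_peak <- check_scalar(window_after_peak, "window_after_peak",
                                      lower = 0, strict_lower = TRUE,
                                      upper = period)
  reltol <- control$reltol %||% 1e-8
  maxit <- control$maxit %||% 500L

  edges <- hist$bin_edges
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  peak_idx <- which.max(hist$counts)  # earliest bin at the maximum
  peak_t <- edges[peak_idx]
  if (is.null(window_after_peak)) {
    win_start <- edges[1]
    win_end <- edges[length(edges)]
    idx <- seq_along(hist$counts)
  } else {
    win_start <- peak_t
    win_end <- min(peak_t + window_after_peak, edges[length(edges)])
    idx <- which(edges[-length(edges)] >= peak_t - 1e-12 &
                   edges[-length(edges)] < win_end - 1e-12)
  }
  cw <- hist$counts[idx]

  fit_irf <- is.null(irf)
  irf0 <- if (fit_irf) irf_model(mids[peak_idx], 0.2, laser_period = period) else irf
  stopifnot(inherits(irf0, "irf_model"))

  # initial lifetimes from the empirical mean arrival time past the peak
  w <- hist$counts[idx]
  m <- sum((mids[idx] - peak_t) * w) / max(sum(w), 1)
  m <- min(max(m, 0.1), 0.8 * period)
  taus0 <- if (n_components == 1L) m else c(0.5 * m, 2 * m)
  th0 <- pack_theta(taus0, 0.5, 1e-3, irf0, fit_background, fit_irf)

  obj_fun <- function(th) {
    pr <- unpack_theta(th, n_components, fit_background, fit_irf, irf0, period)
    model <- tryCatch(
      decay_model(cbind(pr$amps, pr$taus), background_fraction = pr$bg,
                  laser_period = period),
      error = function(e) NULL)
    if (is.null(model)) return(1e12)
    q <- suppressWarnings(expected_decay_curve(model, pr$irf, edges))[idx]
    if (any(!is.finite(q)) || any(q <= 0)) return(1e12)
    s <- sum(cw) / sum(q)
    mu <- s * q
    if (objective == "poisson") sum(mu - cw * log(mu))
    else sum((cw - mu)^2 / pmax(mu, 1))
  }

  # Nelder-Mead with restarts (the restarted simplex escapes the flat
  # background/long-tail direction), then a quasi-Newton polish.
  opt <- stats::optim(th0, obj_fun, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  for (k in 1:3) {
    opt_r <- stats::optim(opt$par, obj_fun, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = maxit))
    improved <- opt$value - opt_r$value > abs(opt$value) * 10 * reltol
    if (opt_r$value <= opt$value) opt <- opt_r
    if (!improved) break
  }
  opt2 <- tryCatch(
    stats::optim(opt$par, obj_fun, method = "BFGS",
                 control = list(reltol = reltol, maxit = 200L)),
    error = function(e) opt)
  if (is.finite(opt2$value) && opt2$value <= opt$value) opt <- opt2
  converged <- opt$convergence == 0 && is.finite(opt$value) && opt$value < 1e12

  pr <- unpack_theta(opt$par, n_components, fit_background, fit_irf, irf0, period)

  # degenerate two-component fit: lifetimes indistinguishable
  if (n_components == 2L &&
      abs(diff(pr$taus)) < 0.02 * mean(pr$taus)) {
    warning("two-component fit degenerate (lifetimes within 2%); ",
            "collapsing to one component", call. = FALSE)
    return(fit_lifetime(hist, irf = irf, n_components = 1L,
                        window_after_peak = window_after_peak,
                        objective = objective, fit_background = fit_background,
                        control = control))
  }

  ord <- order(pr$taus)
  comps <- cbind(amplitude_fraction = pr$amps[ord], lifetime_tau = pr$taus[ord])

  # reduced Pearson chi-square over the window
  model <- decay_model(comps, background_fraction = pr$bg, laser_period = period)
  q <- suppressWarnings(expected_decay_curve(model, pr$irf, edges))[idx]
  mu <- sum(cw) / sum(q) * q
  npar <- length(th0) + 1L  # + profiled scale
  goodness <- sum((cw - mu)^2 / pmax(mu, 1)) / max(length(cw) - npar, 1L)

  out <- list(
    fitted_components = comps,
    fitted_irf = pr$irf,
    fitted_background = pr$bg,
    tau8 = sum(comps[, 1] * comps[, 2]),
    fit_window = c(start = win_start, end = win_end),
    goodness = goodness,
    converged = converged,
    objective = objective,
    n_photons_in_window = sum(cw),
    optim_value = opt$value
  )
  class(out) <- "lifetime_fit"
  out
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Lifetime fit (%s, window %.2f-%.2f ns, %s):\n",
              x$objective, x$fit_window[1], x$fit_window[2],
              if (x$converged) "converged" else "NOT converged"))
  for (i in seq_len(nrow(x$fitted_components)))
    cat(sprintf("  a = %.4f  tau = %.4f ns\n",
                x$fitted_components[i, 1], x$fitted_components[i, 2]))
  cat(sprintf("  background = %.4g, tau8 = %.4f ns, red. chi2 = %.3g\n",
              x$fitted_background, x$tau8, x$goodness))
  invisible(x)
}

#' Extract the tau8 lifetime readout from a fit
#'
#' The amplitude-weighted mean lifetime \eqn{\sum_i a_i \tau_i} of the
#' windowed fit; equal to the single lifetime for mono-exponential fits.
#'
#' @param fit A converged [fit_lifetime()] result.
#' @return The tau8 lifetime (ns).
#' @export
#' @examples
#' # amplitude-weighted mean: 0.7 * 0.4 + 0.3 * 4.5 = 1.63 ns
tau8_from_fit <- function(fit) {
  stopifnot(inherits(fit, "lifetime_fit"))
  if (!isTRUE(fit$converged))
    stop_invalid("fit did not converge; tau8 is undefined")
  sum(fit$fitted_components[, 1] * fit$fitted_components[, 2])
}
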