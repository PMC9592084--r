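# TCSPC decay-curve construction, histogram simulation and lifetime fitting.

test_that("pure background gives uniform bin probabilities", {
  m <- decay_model(list(c(1, 2.0)), background_fraction = 1 - 1e-12)
  p <- expected_decay_curve(m, irf_model(1, 0.2), default_edges(64))
  expect_equal(p, rep(1 / 64, 64), tolerance = 1e-9)
})

test_that("narrow-IRF mono-exponential matches the wrapped-exponential quadrature oracle", {
  edges <- default_edges()
  m <- decay_model(list(c(1, 2.0)))
  p <- expected_decay_curve(m, irf_model(0, 1e-13), edges)
  oracle <- oracle_wrapped_exp_bins(2.0, 0, edges, 12.5)
  expect_lt(max(abs(p - oracle) / oracle), 1e-6)
})

test_that("convolved biexponential matches the FFT convolution oracle", {
  edges <- default_edges()
  comps <- rbind(c(0.5, 1.0), c(0.5, 3.0))
  m <- decay_model(comps)
  irf <- irf_model(1.0, 0.2)
  p <- expected_decay_curve(m, irf, edges)
  oracle <- oracle_convolved_bins(comps, 1.0, 0.2, edges, 12.5)
  expect_lt(max(abs(p - oracle) / oracle), 1e-6)
})

test_that("expected curve sums to one for randomised valid parameters", {
  set.seed(42)
  for (i in 1:20) {
    n_comp <- sample(1:2, 1)
    amps <- runif(n_comp); amps <- amps / sum(amps)
    taus <- runif(n_comp, 0.2, 8)
    m <- decay_model(cbind(amps, taus), background_fraction = runif(1, 0, 0.5))
    irf <- irf_model(runif(1, 0, 12), runif(1, 0.05, 0.5))
    p <- expected_decay_curve(m, irf, default_edges(sample(c(64, 128, 256), 1)))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("invalid inputs are rejected and long lifetimes warn", {
  m <- decay_model(list(c(1, 2)))
  expect_error(expected_decay_curve(m, irf_model(1, 0.2), c(0, 1, 3, 12.5)),
               "uniform")
  expect_error(decay_model(list(c(0.5, 1), c(0.6, 2))), "sum to 1")
  expect_error(decay_model(list(c(1, -2))), "> 0")
  m_long <- decay_model(list(c(1, 1300)))
  expect_warning(expected_decay_curve(m_long, irf_model(1, 0.2),
                                      default_edges()),
                 "ill-conditioned")
})

test_that("histogram simulation is reproducible and validates inputs", {
  m <- decay_model(list(c(1, 2)))
  irf <- irf_model(1, 0.1)
  expect_error(simulate_histogram(m, irf, 0), ">= 1")
  h1 <- simulate_histogram(m, irf, 1e4, seed = 9)
  h2 <- simulate_histogram(m, irf, 1e4, seed = 9)
  expect_identical(h1$counts, h2$counts)
  expect_equal(h1$total_photons, 1e4)
})

test_that("empirical mean arrival time matches the wrapped-exponential closed form", {
  m <- decay_model(list(c(1, 2.0)))
  h <- simulate_histogram(m, irf_model(1.0, 0.05), 1e6, seed = 21)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  emp_mean <- sum(mids * h$counts) / h$total_photons
  expect_equal(emp_mean, oracle_wrapped_exp_mean(2.0, 1.0, 12.5),
               tolerance = 0.01)
})

test_that("noiseless expected counts are fitted back to the generating parameters", {
  irf <- irf_model(1.0, 0.2)
  m <- decay_model(list(c(0.6, 0.8), c(0.4, 3.2)))
  edges <- default_edges()
  counts <- round(1e6 * expected_decay_curve(m, irf, edges))
  h <- tcspc_histogram(edges, counts)
  f <- fit_lifetime(h, irf = irf, n_components = 2)
  expect_true(f$converged)
  taus <- sort(f$fitted_components[, 2])
  expect_lt(abs(taus[1] - 0.8) / 0.8, 0.005)
  expect_lt(abs(taus[2] - 3.2) / 3.2, 0.005)
  tau8_true <- 0.6 * 0.8 + 0.4 * 3.2
  expect_lt(abs(tau8_from_fit(f) - tau8_true) / tau8_true, 0.005)
})

test_that("simulated mono-exponential lifetimes are recovered within 1%", {
  irf <- irf_model(1.0, 0.1)
  m <- decay_model(list(c(1, 2.0)))
  h <- simulate_histogram(m, irf, 1e6, seed = 7)
  f <- fit_lifetime(h, irf = irf, n_components = 1)
  expect_true(f$converged)
  expect_gt(f$fitted_components[, 2], 1.98)
  expect_lt(f$fitted_components[, 2], 2.02)
})

test_that("both fit objectives recover a biexponential at moderate photon counts", {
  irf <- irf_model(1.0, 0.2)
  m <- decay_model(list(c(0.7, 0.4), c(0.3, 4.5)))  # tau8 = 1.63 ns
  h <- simulate_histogram(m, irf, 5e5, seed = 11)
  for (obj in c("poisson", "leastsq")) {
    f <- fit_lifetime(h, irf = irf, n_components = 2, objective = obj)
    expect_true(f$converged)
    expect_lt(abs(tau8_from_fit(f) - 1.63), 0.05)
  }
})

test_that("windowed and full-period fits agree for short decays", {
  irf <- irf_model(1.0, 0.1)
  m <- decay_model(list(c(0.6, 1.0), c(0.4, 3.0)))
  h <- simulate_histogram(m, irf, 1e6, seed = 5)
  f8 <- fit_lifetime(h, irf = irf)
  ff <- fit_lifetime(h, irf = irf, window_after_peak = NULL)
  expect_lt(abs(tau8_from_fit(f8) - tau8_from_fit(ff)) / tau8_from_fit(ff),
            0.02)
  expect_lte(diff(f8$fit_window), 8)
})

test_that("tau8 is the amplitude-weighted mean lifetime", {
  irf <- irf_model(1.0, 0.2)
  mk_fit <- function(comps) {
    counts <- round(1e5 * expected_decay_curve(decay_model(comps), irf,
                                               default_edges()))
    fit_lifetime(tcspc_histogram(default_edges(), counts), irf = irf,
                 n_components = nrow(comps))
  }
  f1 <- mk_fit(cbind(1, 2.0))
  expect_equal(tau8_from_fit(f1), 2.0, tolerance = 1e-3)
  f2 <- mk_fit(rbind(c(0.5, 1.0), c(0.5, 3.0)))
  expect_equal(tau8_from_fit(f2), 2.0, tolerance = 0.01)
  f3 <- mk_fit(rbind(c(0.7, 0.4), c(0.3, 4.5)))
  expect_equal(tau8_from_fit(f3), 1.63, tolerance = 0.01)
  f1$converged <- FALSE
  expect_error(tau8_from_fit(f1), "converge")
})

test_that("tau8 increases with each component lifetime at fixed amplitudes", {
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0.2, 0.8)
    t1 <- runif(1, 0.3, 2); t2 <- runif(1, 2, 6)
    base <- a * t1 + (1 - a) * t2
    expect_gt(a * (t1 + 0.5) + (1 - a) * t2, base)
    expect_gt(a * t1 + (1 - a) * (t2 + 0.5), base)
  }
})

test_that("degenerate two-component fits collapse to one component", {
  irf <- irf_model(1.0, 0.1)
  m <- decay_model(list(c(1, 2.0)))
  h <- simulate_histogram(m, irf, 2e5, seed = 13)
  f <- suppressWarnings(fit_lifetime(h, irf = irf, n_components = 2))
  if (nrow(f$fitted_components) == 1L) {
    expect_equal(f$fitted_components[, 2], 2.0, tolerance = 0.05,
                 ignore_attr = TRUE)
  } else {
    # both lifetimes straddle the true value without degenerating
    expect_lt(abs(tau8_from_fit(f) - 2.0), 0.05)
  }
  expect_error(fit_lifetime(tcspc_histogram(default_edges(16),
                                            rep(1, 16)), irf = irf),
               "photons")
})
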