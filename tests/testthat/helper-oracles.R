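# Independent oracles used by the TCSPC tests.

# Bin probabilities of the *un-convolved* periodic exponential (IRF width ->
# 0, pulse at t0), by numerical integration of the wrapped density
#   d(t) = k exp(-k ((t - t0) mod T)) / (1 - exp(-k T)).
oracle_wrapped_exp_bins <- function(tau, t0, bin_edges, period) {
  k <- 1 / tau
  dens <- function(t) {
    u <- (t - t0) %% period
    k * exp(-k * u) / (1 - exp(-k * period))
  }
  nb <- length(bin_edges) - 1L
  vapply(seq_len(nb), function(i) {
    stats::integrate(dens, bin_edges[i], bin_edges[i + 1L],
                     rel.tol = 1e-10, subdivisions = 400L)$value
  }, numeric(1))
}

# Bin probabilities of the periodic decay convolved with a Gaussian IRF, by
# quadrature over the Gaussian excitation-time density.  G(x) is the
# "unrolled" CDF of the wrapped exponential (one unit of mass per period),
# so the probability that a photon started at s lands in [a, b] (mod the
# period) is G(b - s) - G(a - s); integrating that against the Gaussian
# gives the bin probability without any closed-form convolution.
oracle_convolved_bins <- function(components, t0, sigma, bin_edges, period) {
  unrolled_cdf <- function(x, k) {
    u <- x %% period
    floor(x / period) + (1 - exp(-k * u)) / (1 - exp(-k * period))
  }
  nb <- length(bin_edges) - 1L
  p <- rep(0, nb)
  for (c_i in seq_len(nrow(components))) {
    a_c <- components[c_i, 1]; k <- 1 / components[c_i, 2]
    for (i in seq_len(nb)) {
      f <- function(s)
        stats::dnorm(s, t0, sigma) *
          (unrolled_cdf(bin_edges[i + 1L] - s, k) -
             unrolled_cdf(bin_edges[i] - s, k))
      p[i] <- p[i] + a_c * stats::integrate(f, t0 - 10 * sigma,
                                            t0 + 10 * sigma,
                                            rel.tol = 1e-11,
                                            subdivisions = 400L)$value
    }
  }
  p / sum(p)
}

# Mean photon arrival time over one period for a wrapped exponential excited
# at t0 (closed form; arrival observed modulo the period).
oracle_wrapped_exp_mean <- function(tau, t0, period) {
  k <- 1 / tau
  z <- 1 - exp(-k * period)
  e_u <- 1 / k - period * exp(-k * period) / z
  p_wrap <- (exp(-k * (period - t0)) - exp(-k * period)) / z
  t0 + e_u - period * p_wrap
}

default_edges <- function(n_bins = 256L, period = 12.5) {
  seq(0, period, length.out = n_bins + 1L)
}
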