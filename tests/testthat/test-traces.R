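# Transient quantification, exclusion rules, averaging and comparisons.

mk_trace <- function(times, values, sensor = "SBFI", stim = 60, id = "r1") {
  roi_trace(id, sensor, times, values, stim_time = stim)
}

test_that("delta F/F is zero on constant traces and scale invariant", {
  t <- seq(0, 200, by = 5)
  tr <- mk_trace(t, rep(1000, length(t)))
  d <- delta_f_over_f(tr)
  expect_equal(d$values, rep(0, length(t)))
  expect_identical(d$units, "dff")

  set.seed(1)
  v <- 1000 + cumsum(rnorm(length(t), 0, 5))
  d1 <- delta_f_over_f(mk_trace(t, v))
  d2 <- delta_f_over_f(mk_trace(t, 3.7 * v))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("the SBFI peak dF/F is the minimum relative intensity", {
  t <- seq(0, 200, by = 2)
  v <- rep(1000, length(t))
  v[t >= 60 & t < 90] <- seq(744, 990, length.out = sum(t >= 60 & t < 90))
  d <- delta_f_over_f(mk_trace(t, v))
  m <- transient_metrics(d, polarity = "down")
  expect_equal(m$delta_peak, -0.256, tolerance = 1e-9)
  expect_equal(m$dff_peak, -0.256, tolerance = 1e-9)
})

test_that("half-decay of an exponential transient is recovered by interpolation", {
  # decay half-life 0.41 s sampled at 4 Hz
  t <- seq(0, 120, by = 0.25)
  v <- rep(0, length(t))
  post <- t >= 60
  v[post] <- exp(-(t[post] - 60) * log(2) / 0.41)
  tr <- mk_trace(t, 1000 * (1 + v))
  m <- transient_metrics(tr, polarity = "up")
  expect_equal(m$half_decay_time, 0.41, tolerance = 0.25 / 0.41)
  expect_equal(m$time_to_peak, 0)
})

test_that("flat traces and ramp decays give the stated metrics", {
  t <- seq(0, 200, by = 1)
  m_flat <- transient_metrics(mk_trace(t, rep(5, length(t))), polarity = "up")
  expect_equal(m_flat$delta_peak, 0)
  expect_false(m_flat$half_decay_defined)

  # step up at stimulus, then linear ramp crossing halfway at 10 s after peak
  v <- rep(1, length(t))
  ramp <- t >= 60
  v[ramp] <- pmax(2 - (t[ramp] - 60) * 0.05, 1)  # halfway (1.5) at t = 70
  m <- transient_metrics(mk_trace(t, v), polarity = "up")
  expect_equal(m$half_decay_time, 10, tolerance = 1e-9)
})

test_that("transient metrics are invariant to intensity rescaling after dF/F", {
  t <- seq(0, 200, by = 2)
  set.seed(4)
  v <- 1000 - 200 * exp(-(pmax(t - 60, 0)) / 20) * (t >= 60) + rnorm(length(t))
  m1 <- transient_metrics(delta_f_over_f(mk_trace(t, v)), polarity = "down")
  m2 <- transient_metrics(delta_f_over_f(mk_trace(t, 5 * v)), polarity = "down")
  expect_equal(m1$delta_peak, m2$delta_peak, tolerance = 1e-12)
  expect_equal(m1$half_decay_time, m2$half_decay_time, tolerance = 1e-9)
})

test_that("response ratios apply both exclusion rules and partition inputs", {
  mk_metrics <- function(delta, hd, sensor) {
    structure(list(baseline = 0, delta_peak = delta, dff_peak = NA,
                   time_to_peak = 1, half_decay_time = hd,
                   half_decay_defined = is.finite(hd), polarity = "up",
                   roi_id = "r1", sensor = sensor),
              class = "transient_metrics")
  }
  th <- analysis_thresholds()
  ok <- peredox_rcamp_ratio(mk_metrics(0.024, 50, "Peredox"),
                            mk_metrics(0.20, 20, "RCaMP"), th)
  expect_true(ok$included)
  expect_equal(ok$ratio, 0.12)

  small <- peredox_rcamp_ratio(mk_metrics(0.024, 50, "Peredox"),
                               mk_metrics(0.15, 20, "RCaMP"), th)
  expect_false(small$included)
  expect_match(small$excluded_by, "0.2")

  slow <- peredox_rcamp_ratio(mk_metrics(0.024, 50, "Peredox"),
                              mk_metrics(0.5, 40, "RCaMP"), th)
  expect_false(slow$included)
  expect_match(slow$excluded_by, "35")

  # partition: every pair yields exactly one of ratio / exclusion
  set.seed(8)
  for (i in 1:20) {
    r <- peredox_rcamp_ratio(mk_metrics(runif(1, 0, 0.3), runif(1, 5, 60),
                                        "Peredox"),
                             mk_metrics(runif(1, 0, 1), runif(1, 5, 60),
                                        "RCaMP"), th)
    expect_identical(isTRUE(r$included), is.null(r$excluded_by))
    expect_identical(!isTRUE(r$included), !is.null(r$excluded_by))
  }
})

test_that("binned averaging reproduces identical traces with zero spread", {
  t <- sort(unique(c(seq(0, 200, by = 10), 60 + seq(-2, 5, by = 0.25))))
  v <- sin(t / 30)
  tr <- mk_trace(t, v + 2, sensor = "Peredox")
  av <- bin_and_average(list(tr, tr, tr))
  expect_true(all(av$sd == 0))
  expect_equal(max(abs(av$mean - approx(t - 60, v + 2, av$time)$y)), 0,
               tolerance = 0.01)

  tr1 <- mk_trace(t, rep(1, length(t)))
  tr3 <- mk_trace(t, rep(3, length(t)))
  av2 <- bin_and_average(list(tr1, tr3))
  expect_equal(unique(av2$mean), 2)
  expect_equal(unique(av2$sd), sqrt(2))
  expect_equal(unique(av2$sem), 1)
  expect_error(bin_and_average(list(tr1)), "2 traces")
  expect_error(bin_and_average(list(tr1, mk_trace(t, v, stim = NULL))),
               "stim_time")
})

test_that("cohort averaging recovers a known mean peak within its SEM", {
  set.seed(12)
  t <- seq(0, 200, by = 2)
  n <- 13
  true_peak <- -0.25
  traces <- lapply(seq_len(n), function(i) {
    pk <- true_peak * exp(rnorm(1, 0, 0.1))
    v <- pk * exp(-pmax(t - 60, 0) / 25) * (t >= 60) + rnorm(length(t), 0, 0.005)
    mk_trace(t, v, id = sprintf("c%d", i))
  })
  av <- bin_and_average(traces)
  pk_hat <- min(av$mean)
  sem_at_pk <- av$sem[which.min(av$mean)]
  expect_lt(abs(pk_hat - true_peak), 2 * sem_at_pk + 0.02)
})

test_that("group comparison picks the right branch and handles degenerate pairs", {
  set.seed(33)
  a <- rnorm(30); b <- rnorm(30)
  res <- compare_groups(a, b)
  expect_identical(res$test, "two-sample t-test")
  expect_gt(res$p_value, 0.001)

  res_p <- compare_groups(a, a, paired = TRUE)
  expect_equal(res_p$p_value, 1)
  expect_equal(res_p$statistic, 0)

  heavy <- rcauchy(50)
  res_h <- compare_groups(heavy, rnorm(50))
  expect_identical(res_h$test, "Mann-Whitney")
  expect_false(res_h$normal_a)

  expect_error(compare_groups(1:2, 1:5), "at least 3")
  expect_error(compare_groups(1:4, 1:5, paired = TRUE), "equal length")
})

test_that("box summaries use linear-interpolation percentiles", {
  s <- summarize_box(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  s1 <- summarize_box(7)
  expect_equal(unlist(s1[c("mean", "median", "p5", "p95")]),
               c(mean = 7, median = 7, p5 = 7, p95 = 7))
  sym <- summarize_box(c(-3, -1, 0, 1, 3))
  expect_equal(sym$mean, sym$median)
  expect_error(summarize_box(numeric()), "empty")
})
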