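# Synthetic-experiment generator: latent dynamics, sensor maps, cohorts,
# photon rendering.

quiet_protocol <- function() {
  stimulus_protocol("acsf_stim", channel_na_influx_rate = 0,
                    channel_ca_influx_rate = 0)
}

latent_trace <- function(e, col, sensor, pol = "up") {
  # noise-free trace on the latent grid, for time-scale measurements
  roi_trace("lat", sensor, e$latent$time[-1], e$latent[[col]][-1] + 1e-6,
            stim_time = e$protocol$stim_time)
}

test_that("a zero stimulus leaves all latents at their resting values", {
  e <- simulate_cell(quiet_protocol(), sampling = sampling_spec(t_end = 120),
                     seed = 1)
  expect_equal(max(abs(e$latent$ca - 0.1)), 0)
  expect_equal(max(abs(e$latent$na - 13)), 0)
  expect_equal(max(abs(e$latent$nadh)), 0)
  # sensor traces fluctuate only by measurement noise
  expect_lt(sd(e$traces$peredox$values), 3 * 0.05)
  expect_equal(mean(e$traces$peredox$values), 1.63, tolerance = 0.05)
  expect_equal(mean(e$traces$rcamp$values), 0.88, tolerance = 0.05)
})

test_that("simulation is deterministic for a fixed seed", {
  p <- stimulus_protocol("acsf_stim")
  e1 <- simulate_cell(p, sampling = sampling_spec(t_end = 150), seed = 5)
  e2 <- simulate_cell(p, sampling = sampling_spec(t_end = 150), seed = 5)
  expect_identical(e1$traces$sbfi$values, e2$traces$sbfi$values)
  expect_identical(e1$latent, e2$latent)
})

test_that("control stimulation reaches ~25 mM peak sodium and inverts back within 10%", {
  e <- simulate_cell(stimulus_protocol("acsf_stim"),
                     sampling = sampling_spec(t_end = 300), seed = 3)
  latent_peak <- max(e$latent$na) - 13
  expect_equal(latent_peak, 25, tolerance = 0.05)
  d <- delta_f_over_f(e$traces$sbfi)
  m <- transient_metrics(d, polarity = "down")
  recovered <- na_from_dff(m$delta_peak, e$params$sbfi_calib)
  expect_lt(abs(recovered - latent_peak) / latent_peak, 0.10)
})

test_that("NCX sodium bookkeeping balances calcium clearance", {
  e <- simulate_cell(stimulus_protocol("acsf_stim"),
                     sampling = sampling_spec(t_end = 300), seed = 3)
  expect_lt(abs(e$conservation["ncx_na_cum"] -
                  e$params$ca_to_na_volume_factor *
                  e$conservation["ncx_ca_cum"]) /
              e$conservation["ncx_na_cum"], 0.001)
})

test_that("peak responses are monotone in stimulus strength", {
  peaks <- vapply(c(0.5, 1, 2), function(s) {
    p <- stimulus_protocol("acsf_stim",
                           channel_na_influx_rate = 3.16 * s,
                           channel_ca_influx_rate = 1.0 * s)
    e <- simulate_cell(p, sampling = sampling_spec(t_end = 200), seed = 1)
    c(na = max(e$latent$na), nadh = max(e$latent$nadh))
  }, numeric(2))
  expect_true(all(diff(peaks["na", ]) > 0))
  expect_true(all(diff(peaks["nadh", ]) > 0))
})

test_that("removing external sodium abolishes the NCX term and slows calcium return", {
  p_na <- stimulus_protocol("ca_puff")
  p_0na <- stimulus_protocol("ca_puff", external_na_present = FALSE)
  e_na <- simulate_cell(p_na, sampling = sampling_spec(t_end = 200), seed = 2)
  e_0na <- simulate_cell(p_0na, sampling = sampling_spec(t_end = 200), seed = 2)
  expect_equal(unname(e_0na$conservation["ncx_na_cum"]), 0)
  expect_equal(max(e_0na$latent$na), 13)
  hd <- function(e) transient_metrics(latent_trace(e, "ca", "RCaMP"),
                                      polarity = "up")$half_decay_time
  expect_gt(hd(e_0na), hd(e_na))
})

test_that("calcium puffs raise NADH only with forward NCX and an active pump", {
  s <- sampling_spec(t_end = 200)
  e_ctrl <- simulate_cell(stimulus_protocol("ca_puff"), sampling = s, seed = 2)
  expect_gt(max(e_ctrl$latent$nadh), 0.01)
  e_0na <- simulate_cell(stimulus_protocol("ca_puff",
                                           external_na_present = FALSE),
                         sampling = s, seed = 2)
  expect_equal(max(e_0na$latent$nadh), 0)
  e_ouab <- simulate_cell(stimulus_protocol("ca_puff"),
                          cell_params(pump_vmax = 0), sampling = s, seed = 2)
  expect_equal(max(e_ouab$latent$nadh), 0)
})

test_that("time scales order as calcium < sodium < NADH half-decay", {
  e <- simulate_cell(stimulus_protocol("acsf_stim"), seed = 1)
  hd_ca <- transient_metrics(latent_trace(e, "ca", "RCaMP"),
                             polarity = "up")$half_decay_time
  hd_na <- transient_metrics(latent_trace(e, "na", "SBFI"),
                             polarity = "up")$half_decay_time
  hd_nadh <- transient_metrics(latent_trace(e, "nadh", "Peredox"),
                               polarity = "up")$half_decay_time
  expect_lt(hd_ca, hd_na)
  expect_lt(hd_na, hd_nadh)
})

test_that("blocking calcium entry halves the paired SBFI response", {
  s <- sampling_spec(t_end = 250)
  e_a <- simulate_cell(stimulus_protocol("acsf_stim"), sampling = s, seed = 17)
  e_b <- simulate_cell(stimulus_protocol("cav_block"), sampling = s, seed = 17)
  pk <- function(e) abs(transient_metrics(delta_f_over_f(e$traces$sbfi),
                                          polarity = "down")$delta_peak)
  ratio <- pk(e_b) / pk(e_a)
  expect_gt(ratio, 0.40)
  expect_lt(ratio, 0.65)
})

test_that("cohorts are reproducible, paired and collapse at zero variability", {
  s <- sampling_spec(t_end = 150)
  p <- stimulus_protocol("acsf_stim")
  q <- stimulus_protocol("cav_block")
  c1 <- generate_cohort(3, p, q, sampling = s, seed = 9)
  c2 <- generate_cohort(3, p, q, sampling = s, seed = 9)
  expect_identical(c1$cells[[2]]$a$traces$sbfi$values,
                   c2$cells[[2]]$a$traces$sbfi$values)
  c0 <- generate_cohort(3, p, q,
                        params = cell_params(cell_variability_cv = 0),
                        sampling = s, seed = 9)
  expect_identical(c0$cells[[1]]$a$latent, c0$cells[[3]]$a$latent)
  expect_error(generate_cohort(1, p, q), ">= 2")
})

test_that("amplitude solving and bleed-through wiring in photon rendering", {
  expect_equal(flimion:::solve_amplitudes(1.63, c(0.4, 4.5)),
               c(1 - 0.3, 0.3))
  expect_error(flimion:::solve_amplitudes(5.0, c(0.4, 4.5)), "hull")

  e <- simulate_cell(stimulus_protocol("acsf_stim"),
                     sampling = sampling_spec(t_end = 150,
                                              coarse_dt = 50, fine_dt = 2.5),
                     seed = 1)
  fr0 <- render_photons(e, photons_per_frame = 1e4, bleedthrough = 0,
                        seed = 4)
  fr <- render_photons(e, photons_per_frame = 1e4, bleedthrough = 0.053,
                       seed = 4)
  # zero bleed-through: red carries exactly its own photon budget
  expect_true(all(vapply(fr0, function(x) x$red$total_photons, numeric(1)) == 1e4))
  # same seed: the first frame's pure draws coincide, so the difference is
  # the binomially thinned green leak
  expect_identical(fr0[[1]]$green$counts, fr[[1]]$green$counts)
  bleed <- fr[[1]]$red$counts - fr0[[1]]$red$counts
  expect_true(all(bleed >= 0))
  expect_equal(sum(bleed) / fr[[1]]$green$total_photons, 0.053,
               tolerance = 0.15)
})
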