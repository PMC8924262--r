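# Generators: reproducibility, ground-truth bookkeeping, and the stated
# closed-form identities.

test_that("poking generator honours threshold, saturation and tau", {
  pr <- poking_protocol()

  # sub-threshold step: evoked component identically zero
  g <- gating_params(threshold_um = 3, noise_sd_pa = 0, leak_pa = -5)
  sw <- simulate_poking_sweep(pr, g, step_index = 5, seed = 1)  # 2.0 um
  expect_equal(sweep_meta(sw)$truth$peak_pa, 0)
  expect_equal(sw$current_pa, rep(-5, nrow(sw)), tolerance = 1e-6)

  # saturation: amplitude far above the Boltzmann midpoint recovers i_max
  g2 <- gating_params(threshold_um = 0.2, half_um = 1, slope_um = 0.2,
                      noise_sd_pa = 0, leak_pa = 0, i_max_pa = -800)
  sw2 <- simulate_poking_sweep(pr, g2, step_index = 13, seed = 1)
  expect_equal(max(abs(sw2$current_pa)), 800, tolerance = 0.01)

  # noiseless decay refit by an independent log-linear regression
  g3 <- gating_params(noise_sd_pa = 0, leak_pa = 0, tau_inact_ms = 8)
  sw3 <- simulate_poking_sweep(pr, g3, step_index = 13, seed = 1)
  pk <- which.max(abs(sw3$current_pa))
  end_idx <- attr(sw3, "end_index")
  idx <- (pk + 50):(pk + round(4 * 8 * 200))   # ~4 tau, past filter transient
  tau_hat <- loglinear_tau_ms(sw3$time_s[idx], sw3$current_pa[idx])
  expect_equal(tau_hat, 8, tolerance = 0.01)
})

test_that("poking series covers 13 steps to 5.2 um with monotone responses", {
  pr <- poking_protocol()
  g <- gating_params(noise_sd_pa = 0)
  sweeps <- simulate_poking_series(pr, g, seed = 3)
  expect_length(sweeps, 13)
  amps <- vapply(sweeps, function(s) sweep_meta(s)$amplitude_um, numeric(1))
  expect_equal(max(amps), 5.2)
  peaks <- vapply(sweeps, function(s) abs(sweep_meta(s)$truth$peak_pa), numeric(1))
  expect_true(all(diff(peaks) >= 0))

  # threshold above the largest step: nothing evoked anywhere
  g0 <- gating_params(threshold_um = 6, noise_sd_pa = 0, leak_pa = 0)
  s0 <- simulate_poking_series(pr, g0, seed = 3)
  expect_true(all(vapply(s0, function(s) max(abs(s$current_pa)), numeric(1)) < 1e-6))
})

test_that("generators are bit-reproducible given a seed", {
  pr <- poking_protocol()
  g <- gating_params()
  a <- simulate_poking_sweep(pr, g, 7, seed = 42)
  b <- simulate_poking_sweep(pr, g, 7, seed = 42)
  expect_identical(a$current_pa, b$current_pa)

  pp <- short_pressure_protocol()
  ch <- channel_params()
  expect_identical(simulate_pressure_sweep(pp, ch, -60, seed = 9)$current_pa,
                   simulate_pressure_sweep(pp, ch, -60, seed = 9)$current_pa)

  cfg <- tirf_config(n_frames = 5, frame_shape = c(24, 24))
  mo <- list(list(model = motion_model("diffusion"), x0_um = 1, y0_um = 1))
  expect_identical(simulate_tirf_movie(cfg, mo, seed = 5)$frames,
                   simulate_tirf_movie(cfg, mo, seed = 5)$frames)

  expect_identical(simulate_cell_tables(seed = 11),
                   simulate_cell_tables(seed = 11))
})

test_that("channel-free and saturated patches give the Ohmic identities", {
  pp <- short_pressure_protocol()

  ch0 <- channel_params(n_channels = 0, leak_pa = -1, noise_sd_pa = 0.3)
  sw0 <- simulate_pressure_sweep(pp, ch0, -60, seed = 2)
  n <- nrow(sw0)
  expect_lt(abs(mean(sw0$current_pa) - (-1)), 4 * 0.3 / sqrt(n))

  # one channel pinned open: constant -2.4 pA at g = 24 pS, -100 mV, E_rev 0
  ch1 <- channel_params(unitary_conductance_ps = 24, reversal_mv = 0,
                        n_channels = 1, p_open_half_mmhg = 1e6,
                        mean_open_dwell_ms = 1e7, noise_sd_pa = 0, leak_pa = 0)
  sw1 <- simulate_pressure_sweep(pp, ch1, -60, seed = 2)
  mid <- sw1$current_pa[2000:nrow(sw1)]
  expect_equal(unique(round(mid, 6)), -2.4, tolerance = 1e-6)
})

test_that("Markov gating matches its stationary open probability and dwell mean", {
  pp <- pressure_protocol(step_duration_s = 60, pre_s = 0, post_s = 0)
  ch <- channel_params(n_channels = 1, mean_open_dwell_ms = 4)
  ev <- simulate_gating_events(pp, ch, -60, seed = 13)
  p <- p_open(-60, ch)
  open_frac <- sum(ev$t_close - ev$t_open) / 60
  n_ev <- nrow(ev)
  expect_gt(n_ev, 1000)
  expect_lt(abs(open_frac - p), 3 * sqrt(p * (1 - p) / n_ev))
  dwells <- (ev$t_close - ev$t_open)[ev$complete] * 1000
  expect_lt(abs(mean(dwells) - 4), 3 * 4 / sqrt(length(dwells)))
})

test_that("TIRF movies render background, static spots and Brownian ensembles", {
  cfg <- tirf_config(n_frames = 4, frame_shape = c(24, 24), noise_sd = 2)
  empty <- simulate_tirf_movie(cfg, list(), seed = 1)
  expect_equal(mean(empty$frames), cfg$background, tolerance = 0.1)
  expect_lt(sd(empty$frames), 3)

  still <- simulate_tirf_movie(
    cfg, list(list(model = motion_model("diffusion", d_um2_s = 0),
                   x0_um = 1.2, y0_um = 0.9)), seed = 1)
  expect_equal(unique(still$truth$x_um), 1.2)
  expect_equal(unique(still$truth$y_um), 0.9)

  expect_error(
    simulate_tirf_movie(cfg, list(list(model = motion_model("diffusion"),
                                       x0_um = 99, y0_um = 1))),
    "outside")

  # ensemble time-averaged MSD of Brownian ground truth vs 4 D tau
  withr::with_seed(21, {
    D <- 0.05; dt <- 0.1
    msds <- purrr::map(1:200, function(i) {
      tr <- simulate_trajectory(motion_model("diffusion", d_um2_s = D),
                                n_frames = 100, dt_s = dt)
      compute_msd(tr, frame_rate_hz = 10)$msd_um2[1:5]
    })
    mean_msd <- Reduce(`+`, msds) / 200
    expected <- 4 * D * (1:5) * dt
    expect_true(all(abs(mean_msd - expected) / expected < 0.15))
  })
})

test_that("cell-table generator reproduces its configured rates", {
  spec0 <- tibble::tibble(group = "g", n_cells = 50, p_responder = 0,
                          p_bearing = NA, neurite_mean_um = NA,
                          neurite_sd_log = NA, count_lambda = NA)
  expect_equal(sum(simulate_cell_tables(spec0, seed = 1)$responder), 0)
  spec1 <- dplyr::mutate(spec0, p_responder = 1)
  expect_equal(sum(simulate_cell_tables(spec1, seed = 1)$responder), 50)

  spec <- dplyr::mutate(spec0, n_cells = 10000, p_responder = 0.21)
  frac <- mean(simulate_cell_tables(spec, seed = 7)$responder)
  expect_lt(abs(frac - 0.21), 3 * sqrt(0.21 * 0.79 / 10000))

  bad <- dplyr::mutate(spec0, p_responder = 1.2)
  expect_error(simulate_cell_tables(bad, seed = 1), "probabilities")
})
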