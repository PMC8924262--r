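# Whole-cell poking analysis.

test_that("subtract_leak zeroes the baseline and records the offset", {
  sw <- make_test_sweep(rep(-5, 1000))
  out <- subtract_leak(sw)
  expect_equal(out$current_pa, rep(0, 1000))
  expect_equal(sweep_meta(out)$leak_subtracted_pa, -5)

  # already-zero baseline: identity
  sw0 <- make_test_sweep(rep(0, 1000))
  expect_equal(subtract_leak(sw0)$current_pa, sw0$current_pa, tolerance = 1e-12)

  # noise-only baseline: exact zero mean over the baseline window
  withr::with_seed(4, {
    sw_n <- make_test_sweep(rnorm(4000, -3, 0.5))
    out_n <- subtract_leak(sw_n)
    idx <- piezoquant:::baseline_indices(out_n)
    expect_equal(mean(out_n$current_pa[idx]), 0, tolerance = 1e-12)
    # sampling bound includes the variance of the subtracted baseline mean
    expect_lt(abs(mean(out_n$current_pa)),
              4 * 0.5 * sqrt(1 / 4000 + 1 / length(idx)))
  })

  # window too short
  sw_short <- make_test_sweep(rep(0, 100), pre_ms = 5)
  expect_error(subtract_leak(sw_short), "10")
})

test_that("peak_current returns the signed extremum of largest magnitude", {
  y <- rep(0, 1000); y[400] <- -200
  sw <- make_test_sweep(y)
  expect_equal(peak_current(sw), -200)
  expect_equal(peak_current(make_test_sweep(rep(0, 1000))), 0)
  expect_error(peak_current(sw, window = c(10, 5)), "window")
})

test_that("onset detection implements the k-SD rule with latency-derived threshold", {
  # flat noise-free trace: nothing detected (needs an SD floor)
  sw_flat <- make_test_sweep(rep(0, 2000))
  expect_error(detect_onset(sw_flat), "degenerate")
  expect_false(detect_onset(sw_flat, min_sd = 0.1)$detected)

  # constructed crossing: step to -20 pA 3 ms after ramp start, sd = 1
  withr::with_seed(9, {
    fs <- 10  # kHz
    n <- 2000
    y <- rnorm(n, 0, 1)
    onset <- 201L
    y[(onset + 3 * fs):n] <- y[(onset + 3 * fs):n] - 20
    stim <- numeric(n); stim[onset:n] <- 10   # ample ramp, no clamping
    sw <- make_test_sweep(y, sampling_khz = fs, pre_ms = 20, stim_ms = 100,
                          stimulus = stim)
    res <- detect_onset(sw, ramp_speed_um_ms = 1)
    expect_true(res$detected)
    expect_equal(res$latency_ms, 3, tolerance = 0.25)
    expect_equal(res$threshold_um, res$latency_ms * 1)
  })

  # simulated noiseless sweep: threshold recovered within one sample
  # equivalent plus the characterized filter-delay allowance
  pr <- poking_protocol()
  g <- gating_params(threshold_um = 2, noise_sd_pa = 0)
  sw2 <- subtract_leak(simulate_poking_sweep(pr, g, step_index = 13, seed = 1))
  res2 <- detect_onset(sw2, ramp_speed_um_ms = 1, min_sd = 0.01)
  allowance <- 0.005 + filter_delay_ms(2.9, 200) * 1
  expect_lt(abs(res2$threshold_um - 2), allowance)
})

test_that("threshold recovery error shrinks as noise vanishes", {
  pr <- poking_protocol()
  errs <- vapply(c(20, 5, 0.5), function(nsd) {
    g <- gating_params(threshold_um = 2.4, noise_sd_pa = nsd)
    res <- purrr::map_dbl(1:5, function(i) {
      sw <- subtract_leak(simulate_poking_sweep(pr, g, 13, seed = 100 + i))
      detect_onset(sw, 1, min_sd = 0.01)$threshold_um
    })
    mean(abs(res - 2.4))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("onset rule at 6 SD keeps the false-positive rate below 1%", {
  withr::with_seed(60, {
    n_pre <- 10000L; n_stim <- 2000L
    fp <- purrr::map_lgl(1:1000, function(i) {
      y <- rnorm(n_pre + n_stim)
      sw <- make_test_sweep(y, sampling_khz = 200, pre_ms = 50, stim_ms = 10)
      detect_onset(sw, 1)$detected
    })
    expect_lt(mean(fp), 0.01)
  })
})

test_that("inactivation fit recovers tau and rejects flat decays", {
  # pure exponential, noiseless
  fs <- 50
  t_ms <- (0:4999) / fs
  y <- numeric(20 * fs)                      # 20 ms flat baseline
  decay <- -300 * exp(-t_ms / 10)            # tau = 10 ms
  sw <- make_test_sweep(c(y, decay), sampling_khz = fs, pre_ms = 19,
                        stim_ms = 90)
  fit <- fit_inactivation(sw, fit_window = c(length(y) + 1L, length(y) + 3000L))
  expect_true(fit$converged)
  expect_equal(fit$tau_inact_ms, 10, tolerance = 1e-3)
  expect_equal(glance(fit)$tau_inact_ms, fit$tau_inact_ms)
  expect_equal(nrow(tidy(fit)), 3)

  # constant trace: no decay component
  sw_flat <- make_test_sweep(rep(-100, 3000), sampling_khz = fs)
  expect_error(fit_inactivation(sw_flat, fit_window = c(500, 2500)),
               "no decay component")

  # noisy exponential vs the independent log-linear oracle on the clean decay
  withr::with_seed(17, {
    tau_true <- 6
    clean <- -400 * exp(-t_ms / tau_true)
    tau_oracle <- loglinear_tau_ms(t_ms / 1000, clean)
    noisy <- clean + rnorm(length(clean), 0, 0.05 * 400)
    swn <- make_test_sweep(c(y, noisy), sampling_khz = fs, pre_ms = 19,
                           stim_ms = 90)
    fitn <- fit_inactivation(swn, fit_window = c(length(y) + 1L,
                                                 length(y) + 3000L))
    expect_lt(abs(fitn$tau_inact_ms - tau_oracle) / tau_oracle, 0.05)
  })
})

test_that("tau recovery stays accurate across the physiological grid", {
  pr <- poking_protocol()
  errs <- purrr::map_dbl(1:20, function(i) {
    tau <- c(2, 5, 10, 20)[(i - 1) %% 4 + 1]
    g <- gating_params(tau_inact_ms = tau, noise_sd_pa = 0.05 * 1050)
    sw <- subtract_leak(simulate_poking_sweep(pr, g, 13, seed = 200 + i))
    fit <- fit_inactivation(sw)
    abs(fit$tau_inact_ms - tau) / tau
  })
  expect_lt(median(errs), 0.05)
})

test_that("displacement-response curves follow the generator and flag silence", {
  pr <- poking_protocol()
  g <- gating_params(noise_sd_pa = 0)
  sweeps <- lapply(simulate_poking_series(pr, g, seed = 5), subtract_leak)
  drc <- displacement_response(sweeps)
  expect_equal(nrow(drc), 13)
  expect_true(all(diff(drc$peak_pa) >= -1e-6))
  expect_s3_class(autoplot(drc), "ggplot")

  # all sub-threshold: flagged as no response
  g0 <- gating_params(threshold_um = 9, noise_sd_pa = 2)
  s0 <- lapply(simulate_poking_series(pr, g0, seed = 6), subtract_leak)
  d0 <- displacement_response(s0)
  expect_true(all(!d0$responded))

  # single sweep: single-point curve; empty input errors
  expect_equal(nrow(displacement_response(sweeps[13])), 1)
  expect_error(displacement_response(list()), "empty")

  # leak-offset invariance: adding a constant changes nothing downstream
  shifted <- lapply(simulate_poking_series(pr, g, seed = 5), function(sw) {
    sw$current_pa <- sw$current_pa + 40
    subtract_leak(sw)
  })
  expect_equal(displacement_response(shifted)$peak_pa, drc$peak_pa,
               tolerance = 1e-9)
})

test_that("velocity ratio applies the CV exclusion rule and recovers the generator", {
  tbl <- tibble::tibble(velocity_um_ms = c(1, 1, 1, 0.25),
                        amplitude_pa = c(500, 500, 500, 500))
  res <- velocity_ratio(tbl)
  expect_equal(res$ratio, 1)
  expect_false(res$excluded)

  tbl2 <- tibble::tibble(velocity_um_ms = c(1, 1, 1, 0.25),
                         amplitude_pa = c(1000, 1000, 1500, 400))
  res2 <- velocity_ratio(tbl2)
  expect_equal(res2$stability_cv, sd(c(1, 1, 1.5)) / mean(c(1, 1, 1.5)),
               tolerance = 1e-9)
  expect_true(res2$excluded)

  expect_error(velocity_ratio(tbl[1:3, ]), "test velocity")
  expect_error(velocity_ratio(tbl[c(1, 2, 4), ]), "reference")

  # generator: V(0.25)/V(1) = 0.4 by default, matching currents ~60% smaller
  # at the slow velocity
  g <- gating_params(noise_sd_pa = 2)
  amp_at <- function(v, seed) {
    pr <- poking_protocol(n_steps = 9, ramp_speed_um_ms = v)
    abs(peak_current(subtract_leak(simulate_poking_sweep(pr, g, 9, seed))))
  }
  amps <- tibble::tibble(
    velocity_um_ms = c(1, 1, 1, 0.25, 0.25),
    amplitude_pa = c(amp_at(1, 31), amp_at(1, 32), amp_at(1, 33),
                     amp_at(0.25, 34), amp_at(0.25, 35)))
  res3 <- velocity_ratio(amps)
  expect_false(res3$excluded)
  expect_equal(res3$ratio, 0.40, tolerance = 0.05)
})

test_that("reversal potential interpolates the zero crossing", {
  iv1 <- tibble::tibble(voltage_mv = seq(-60, 60, 30),
                        peak_pa = seq(-60, 60, 30))
  expect_equal(reversal_potential(iv1)$e_rev_mv, 0)

  iv2 <- tibble::tibble(voltage_mv = seq(-60, 60, 30),
                        peak_pa = seq(-60, 60, 30) - 10)
  expect_equal(reversal_potential(iv2)$e_rev_mv, 10)

  expect_error(reversal_potential(iv1[1, ]), "at least 2")

  # simulated macroscopic currents with configured E_rev = +8 mV
  e_rev <- 8
  iv3 <- purrr::map_dfr(seq(-60, 60, 30), function(v) {
    pr <- poking_protocol(holding_mv = v)
    g <- gating_params(i_max_pa = 15 * (v - e_rev), noise_sd_pa = 1)
    sw <- subtract_leak(simulate_poking_sweep(pr, g, 13, seed = 40 + v))
    tibble::tibble(voltage_mv = v, peak_pa = peak_current(sw))
  })
  expect_lt(abs(reversal_potential(iv3)$e_rev_mv - 8), 2)
})
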