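# Synthetic whole-cell poking recordings.
#
# The generator emulates the standard mechano-clamp protocol: a fire-polished
# probe indents the cell in a series of ramp-and-hold displacement steps of
# increasing amplitude while the whole-cell current is recorded at high
# bandwidth. The evoked-current model is deliberately simple and fully
# parameterised, and every sweep carries its generative parameters in
# metadata so analysis results can be checked against ground truth.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.finite(seed)) abort("`seed` must be a finite integer.")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  withr::defer({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, envir = env)
  set.seed(as.integer(seed))
  invisible(NULL)
}

check_finite <- function(...) {
  vals <- list(...)
  bad <- names(vals)[!vapply(vals, function(v) all(is.finite(v)), logical(1))]
  if (length(bad)) {
    abort(paste0("invalid parameter(s): ", paste(bad, collapse = ", "),
                 " must be finite."))
  }
}

#' Ramp-and-hold indentation protocol
#'
#' Defaults reproduce the standard poking series: 13 steps in 0.4 um
#' increments delivered at 1 um/ms, sampled at 200 kHz and low-pass filtered
#' at 2.9 kHz, holding at -60 mV.
#'
#' @param n_steps Number of displacement steps.
#' @param step_increment_um Displacement increment per step (um).
#' @param ramp_speed_um_ms Probe velocity during the ramp (um/ms).
#' @param hold_duration_ms Hold phase duration (ms).
#' @param pre_stimulus_ms Pre-stimulus baseline duration (ms).
#' @param post_stimulus_ms Trace tail after probe retraction (ms).
#' @param sampling_khz Sampling rate (kHz).
#' @param filter_khz Low-pass cutoff (kHz); must be below Nyquist.
#' @param holding_mv Holding potential (mV).
#' @return A list of class `pq_poking_protocol`.
#' @export
poking_protocol <- function(n_steps = 13, step_increment_um = 0.4,
                            ramp_speed_um_ms = 1, hold_duration_ms = 150,
                            pre_stimulus_ms = 50, post_stimulus_ms = 10,
                            sampling_khz = 200, filter_khz = 2.9,
                            holding_mv = -60) {
  check_finite(n_steps = n_steps, step_increment_um = step_increment_um,
               ramp_speed_um_ms = ramp_speed_um_ms,
               hold_duration_ms = hold_duration_ms,
               pre_stimulus_ms = pre_stimulus_ms,
               post_stimulus_ms = post_stimulus_ms,
               sampling_khz = sampling_khz, filter_khz = filter_khz,
               holding_mv = holding_mv)
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  if (step_increment_um <= 0) abort("`step_increment_um` must be > 0.")
  if (ramp_speed_um_ms <= 0) abort("`ramp_speed_um_ms` must be > 0.")
  if (sampling_khz <= 2 * filter_khz) {
    abort("`sampling_khz` must exceed twice `filter_khz`.")
  }
  structure(list(n_steps = as.integer(n_steps),
                 step_increment_um = step_increment_um,
                 ramp_speed_um_ms = ramp_speed_um_ms,
                 hold_duration_ms = hold_duration_ms,
                 pre_stimulus_ms = pre_stimulus_ms,
                 post_stimulus_ms = post_stimulus_ms,
                 sampling_khz = sampling_khz,
                 filter_khz = filter_khz,
                 holding_mv = holding_mv),
            class = "pq_poking_protocol")
}

#' Generative parameters of the poking-current model
#'
#' The evoked current is zero until the probe displacement crosses
#' `threshold_um`; it then follows `i_max_pa * B(x) * V(v)`, where `B` is a
#' Boltzmann displacement-response function with midpoint `half_um` and slope
#' `slope_um`, and `V` is a Hill velocity-scaling function normalized to 1 at
#' the reference velocity of 1 um/ms. During the hold phase the current
#' decays mono-exponentially with time constant `tau_inact_ms`.
#'
#' @param threshold_um Mechanical activation threshold (um).
#' @param i_max_pa Saturating peak current (pA, negative = inward).
#' @param half_um,slope_um Midpoint and slope of the Boltzmann
#'   displacement-response function (um).
#' @param velocity_half,velocity_hill Half-activation velocity (um/ms) and
#'   Hill coefficient of the velocity-scaling function. The defaults give a
#'   0.25 um/ms : 1 um/ms amplitude ratio of 0.4, i.e. currents ~60% smaller
#'   at the slow velocity.
#' @param tau_inact_ms Inactivation time constant (ms).
#' @param leak_pa Constant leak current (pA).
#' @param noise_sd_pa Gaussian noise SD before filtering (pA).
#' @return A list of class `pq_gating_params`.
#' @export
gating_params <- function(threshold_um = 2.8, i_max_pa = -1200,
                          half_um = 4.2, slope_um = 0.5,
                          velocity_half = 1, velocity_hill = 1,
                          tau_inact_ms = 6, leak_pa = -20, noise_sd_pa = 8) {
  check_finite(threshold_um = threshold_um, i_max_pa = i_max_pa,
               half_um = half_um, slope_um = slope_um,
               velocity_half = velocity_half, velocity_hill = velocity_hill,
               tau_inact_ms = tau_inact_ms, leak_pa = leak_pa,
               noise_sd_pa = noise_sd_pa)
  if (tau_inact_ms <= 0) abort("`tau_inact_ms` must be > 0.")
  if (noise_sd_pa < 0) abort("`noise_sd_pa` must be >= 0.")
  structure(list(threshold_um = threshold_um, i_max_pa = i_max_pa,
                 half_um = half_um, slope_um = slope_um,
                 velocity_half = velocity_half, velocity_hill = velocity_hill,
                 tau_inact_ms = tau_inact_ms, leak_pa = leak_pa,
                 noise_sd_pa = noise_sd_pa),
            class = "pq_gating_params")
}

# Boltzmann displacement-response, in (0, 1)
boltzmann_response <- function(x_um, gating) {
  1 / (1 + exp(-(x_um - gating$half_um) / gating$slope_um))
}

# Hill velocity scaling, normalized to 1 at the 1 um/ms reference velocity
velocity_scale <- function(v_um_ms, gating) {
  h <- gating$velocity_hill
  a <- gating$velocity_half^h
  (v_um_ms^h / (v_um_ms^h + a)) * (1 + a)
}

#' Simulate one poking sweep
#'
#' @param protocol A [poking_protocol()].
#' @param gating A [gating_params()].
#' @param step_index Which step of the series to simulate (1-based); the
#'   commanded displacement is `step_index * step_increment_um`.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   `(protocol, gating, step_index, seed)`.
#' @return A [new_sweep()] whose `stimulus` column is the commanded
#'   displacement (um) and whose metadata stores the ground truth.
#' @export
simulate_poking_sweep <- function(protocol, gating, step_index = 1,
                                  seed = NULL) {
  stopifnot(inherits(protocol, "pq_poking_protocol"),
            inherits(gating, "pq_gating_params"))
  if (step_index < 1 || step_index > protocol$n_steps) {
    abort("`step_index` must be in [1, n_steps].")
  }
  local_seed(seed)
  fs <- protocol$sampling_khz            # samples per ms
  amp <- protocol$step_increment_um * step_index
  ramp_ms <- amp / protocol$ramp_speed_um_ms
  n_pre <- round(protocol$pre_stimulus_ms * fs)
  n_ramp <- round(ramp_ms * fs)
  n_hold <- round(protocol$hold_duration_ms * fs)
  n_post <- round(protocol$post_stimulus_ms * fs)
  n <- n_pre + n_ramp + n_hold + n_post
  t_ms <- (seq_len(n) - 1) / fs

  onset <- n_pre + 1L
  hold_start <- n_pre + n_ramp + 1L
  end_idx <- n_pre + n_ramp + n_hold

  x <- numeric(n)
  if (n_ramp > 0) {
    x[onset:(hold_start - 1L)] <-
      protocol$ramp_speed_um_ms * (t_ms[onset:(hold_start - 1L)] - t_ms[onset])
  }
  x[hold_start:end_idx] <- amp

  evoked <- numeric(n)
  vmult <- velocity_scale(protocol$ramp_speed_um_ms, gating)
  if (amp >= gating$threshold_um) {
    active <- x >= gating$threshold_um & seq_len(n) <= end_idx
    ramp_active <- active & seq_len(n) < hold_start
    evoked[ramp_active] <- gating$i_max_pa * vmult *
      boltzmann_response(x[ramp_active], gating)
    peak <- gating$i_max_pa * vmult * boltzmann_response(amp, gating)
    hold_idx <- hold_start:end_idx
    evoked[hold_idx] <- peak *
      exp(-(t_ms[hold_idx] - t_ms[hold_start]) / gating$tau_inact_ms)
  }

  current <- evoked + gating$leak_pa
  if (gating$noise_sd_pa > 0) current <- current + rnorm(n, 0, gating$noise_sd_pa)
  current <- filter_trace(current, protocol$filter_khz, protocol$sampling_khz)

  new_sweep(time_s = t_ms / 1000, current_pa = current, stimulus = x,
            sampling_khz = protocol$sampling_khz,
            holding_mv = protocol$holding_mv,
            onset_index = onset, end_index = end_idx,
            meta = list(kind = "poking", step_index = step_index,
                        amplitude_um = amp,
                        ramp_speed_um_ms = protocol$ramp_speed_um_ms,
                        truth = c(unclass(gating),
                                  list(velocity_multiplier = vmult,
                                       peak_pa = if (amp >= gating$threshold_um)
                                         gating$i_max_pa * vmult *
                                           boltzmann_response(amp, gating)
                                       else 0))))
}

#' Simulate a full poking series
#'
#' One sweep per protocol step, amplitudes `step_increment_um * (1..n_steps)`.
#' With `noise_sd_pa = 0` the peak magnitudes are non-decreasing with
#' displacement by construction of the Boltzmann response.
#'
#' @inheritParams simulate_poking_sweep
#' @return A list of [new_sweep()] objects, one per step.
#' @export
simulate_poking_series <- function(protocol, gating, seed = NULL) {
  base <- if (is.null(seed)) NULL else as.integer(seed)
  lapply(seq_len(protocol$n_steps), function(i) {
    s <- if (is.null(base)) NULL else base + i
    simulate_poking_sweep(protocol, gating, step_index = i, seed = s)
  })
}
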