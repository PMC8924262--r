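# Synthetic cell-attached pressure-clamp recordings.
#
# Channels in the patch are modelled as independent two-state (closed/open)
# continuous-time Markov chains whose stationary open probability follows a
# Boltzmann function of the applied negative pressure. Each open channel
# contributes one unitary current i = g * (V - E_rev) / 1000 pA. The
# generator keeps full event bookkeeping (open intervals, dwell times, total
# open time) in the sweep metadata so charge-transfer and histogram analyses
# can be validated against ground truth.

#' Negative-pressure step protocol
#'
#' Defaults reproduce the standard stimulus set: 3-s steps at -20 to -80
#' mmHg, holding at -100 mV, 50 kHz sampling, 2.9 kHz low-pass.
#'
#' @param pressure_steps_mmhg Pressures of the step series (mmHg, all <= 0).
#' @param step_duration_s Duration of each pressure step (s).
#' @param pre_s,post_s Stimulus-free baseline before and after the step (s).
#' @param holding_mv Holding potential (mV).
#' @param sampling_khz Sampling rate (kHz).
#' @param filter_khz Low-pass cutoff (kHz).
#' @return A list of class `pq_pressure_protocol`.
#' @export
pressure_protocol <- function(pressure_steps_mmhg = c(-20, -40, -60, -80),
                              step_duration_s = 3, pre_s = 0.5, post_s = 0.5,
                              holding_mv = -100, sampling_khz = 50,
                              filter_khz = 2.9) {
  check_finite(pressure_steps_mmhg = pressure_steps_mmhg,
               step_duration_s = step_duration_s, pre_s = pre_s,
               post_s = post_s, holding_mv = holding_mv,
               sampling_khz = sampling_khz, filter_khz = filter_khz)
  if (any(pressure_steps_mmhg > 0)) abort("pressures must be <= 0 (suction).")
  if (step_duration_s <= 0) abort("`step_duration_s` must be > 0.")
  if (sampling_khz <= 2 * filter_khz) {
    abort("`sampling_khz` must exceed twice `filter_khz`.")
  }
  structure(list(pressure_steps_mmhg = pressure_steps_mmhg,
                 step_duration_s = step_duration_s,
                 pre_s = pre_s, post_s = post_s,
                 holding_mv = holding_mv, sampling_khz = sampling_khz,
                 filter_khz = filter_khz),
            class = "pq_pressure_protocol")
}

#' Generative parameters of the stretch-activated channel model
#'
#' @param unitary_conductance_ps Unitary conductance g (pS).
#' @param reversal_mv Reversal potential (mV).
#' @param n_channels Number of channels in the patch (>= 0).
#' @param p_open_half_mmhg Pressure of half-maximal open probability (mmHg).
#' @param p_open_slope_mmhg Slope of the Boltzmann P_open(pressure) (mmHg).
#' @param mean_open_dwell_ms Mean open dwell time (ms).
#' @param leak_pa Constant leak current (pA).
#' @param noise_sd_pa Gaussian noise SD before filtering (pA).
#' @return A list of class `pq_channel_params`.
#' @export
channel_params <- function(unitary_conductance_ps = 23.4, reversal_mv = 0,
                           n_channels = 5, p_open_half_mmhg = -45,
                           p_open_slope_mmhg = 12, mean_open_dwell_ms = 5,
                           leak_pa = 0, noise_sd_pa = 0.3) {
  check_finite(unitary_conductance_ps = unitary_conductance_ps,
               reversal_mv = reversal_mv, n_channels = n_channels,
               p_open_half_mmhg = p_open_half_mmhg,
               p_open_slope_mmhg = p_open_slope_mmhg,
               mean_open_dwell_ms = mean_open_dwell_ms,
               leak_pa = leak_pa, noise_sd_pa = noise_sd_pa)
  if (unitary_conductance_ps <= 0) abort("`unitary_conductance_ps` must be > 0.")
  if (n_channels < 0) abort("`n_channels` must be >= 0.")
  if (p_open_slope_mmhg <= 0) abort("`p_open_slope_mmhg` must be > 0.")
  if (mean_open_dwell_ms <= 0) abort("`mean_open_dwell_ms` must be > 0.")
  structure(list(unitary_conductance_ps = unitary_conductance_ps,
                 reversal_mv = reversal_mv,
                 n_channels = as.integer(n_channels),
                 p_open_half_mmhg = p_open_half_mmhg,
                 p_open_slope_mmhg = p_open_slope_mmhg,
                 mean_open_dwell_ms = mean_open_dwell_ms,
                 leak_pa = leak_pa, noise_sd_pa = noise_sd_pa),
            class = "pq_channel_params")
}

#' Stationary open probability at a given pressure
#'
#' Boltzmann function of pressure: more negative pressure (stronger suction)
#' yields a higher open probability.
#'
#' @param pressure_mmhg Applied pressure (mmHg, <= 0).
#' @param channels A [channel_params()].
#' @return Open probability in `[0, 1]`.
#' @export
p_open <- function(pressure_mmhg, channels) {
  1 / (1 + exp((pressure_mmhg - channels$p_open_half_mmhg) /
                 channels$p_open_slope_mmhg))
}

# Simulate one channel's closed/open trajectory through consecutive pressure
# segments. `segments` is a data.frame with columns duration_s and p (the
# stationary open probability in that segment). Exploits memorylessness:
# dwells are re-drawn at segment boundaries with the new rates.
simulate_channel_path <- function(segments, close_rate) {
  t0 <- 0
  p1 <- segments$p[1]
  state <- runif(1) < p1   # TRUE = open, stationary start
  open_start <- if (state) 0 else NA_real_
  intervals <- list()
  for (k in seq_len(nrow(segments))) {
    p <- segments$p[k]
    t_end <- t0 + segments$duration_s[k]
    open_rate <- if (p >= 1 - 1e-12) Inf else close_rate * p / (1 - p)
    t <- t0
    repeat {
      rate <- if (state) close_rate else open_rate
      if (rate <= 0) { t <- t_end; break }      # absorbed closed
      if (!is.finite(rate)) {                   # p ~ 1: stays open
        if (!state) { state <- TRUE; open_start <- t }
        t <- t_end
        break
      }
      dwell <- rexp(1, rate)
      if (t + dwell >= t_end) { t <- t_end; break }
      t <- t + dwell
      if (state) {
        intervals[[length(intervals) + 1L]] <- c(open_start, t)
        state <- FALSE
      } else {
        state <- TRUE
        open_start <- t
      }
    }
    t0 <- t_end
  }
  if (state) intervals[[length(intervals) + 1L]] <- c(open_start, t0, NA)
  if (!length(intervals)) {
    return(tibble(t_open = numeric(), t_close = numeric(),
                  complete = logical()))
  }
  m <- do.call(rbind, lapply(intervals, function(v) c(v[1], v[2], length(v) < 3)))
  tibble(t_open = m[, 1], t_close = m[, 2], complete = as.logical(m[, 3]))
}

#' Simulate stochastic gating events
#'
#' Runs the two-state Markov model for every channel across the pre-stimulus,
#' stimulus and post-stimulus segments and returns all open intervals.
#'
#' @inheritParams simulate_pressure_sweep
#' @param duration_s Optional override of the stimulus segment duration.
#' @return A tibble with columns `channel`, `t_open`, `t_close` (s, sweep
#'   time) and `complete` (FALSE when the opening was truncated by the sweep
#'   end).
#' @export
simulate_gating_events <- function(protocol, channels, pressure_mmhg,
                                   seed = NULL, duration_s = NULL) {
  local_seed(seed)
  stim_s <- duration_s %||% protocol$step_duration_s
  segments <- data.frame(
    duration_s = c(protocol$pre_s, stim_s, protocol$post_s),
    p = c(p_open(0, channels), p_open(pressure_mmhg, channels),
          p_open(0, channels)))
  segments <- segments[segments$duration_s > 0, , drop = FALSE]
  close_rate <- 1000 / channels$mean_open_dwell_ms  # s^-1
  out <- lapply(seq_len(channels$n_channels), function(ch) {
    ev <- simulate_channel_path(segments, close_rate)
    if (nrow(ev)) ev$channel <- ch
    ev
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(t_open = numeric(), t_close = numeric(),
                  complete = logical(), channel = integer())
  }
  dplyr::relocate(out, "channel")
}

#' Simulate one pressure-clamp sweep
#'
#' @param protocol A [pressure_protocol()].
#' @param channels A [channel_params()].
#' @param pressure_mmhg Applied pressure for the stimulus step (mmHg, <= 0).
#'   `0` yields a stimulus-free baseline sweep.
#' @param seed Integer seed for bit-reproducibility.
#' @return A [new_sweep()]; `stimulus` is the commanded pressure trace and the
#'   metadata holds the event bookkeeping (`truth$events`, total open time and
#'   unitary current).
#' @export
simulate_pressure_sweep <- function(protocol, channels, pressure_mmhg,
                                    seed = NULL) {
  stopifnot(inherits(protocol, "pq_pressure_protocol"),
            inherits(channels, "pq_channel_params"))
  if (pressure_mmhg > 0) abort("`pressure_mmhg` must be <= 0.")
  local_seed(seed)

  fs_hz <- protocol$sampling_khz * 1000
  dur_s <- protocol$pre_s + protocol$step_duration_s + protocol$post_s
  n <- round(dur_s * fs_hz)
  t_s <- (seq_len(n) - 1) / fs_hz
  onset <- round(protocol$pre_s * fs_hz) + 1L
  end_idx <- round((protocol$pre_s + protocol$step_duration_s) * fs_hz)

  events <- simulate_gating_events(protocol, channels, pressure_mmhg)

  unitary_pa <- channels$unitary_conductance_ps *
    (protocol$holding_mv - channels$reversal_mv) / 1000

  n_open <- numeric(n + 1L)
  if (nrow(events)) {
    ia <- pmin(n + 1L, floor(events$t_open * fs_hz) + 1L)
    ib <- pmin(n + 1L, floor(events$t_close * fs_hz) + 1L)
    for (k in seq_along(ia)) {
      n_open[ia[k]] <- n_open[ia[k]] + 1
      n_open[ib[k]] <- n_open[ib[k]] - 1
    }
  }
  n_open <- cumsum(n_open)[seq_len(n)]

  current <- channels$leak_pa + unitary_pa * n_open
  if (channels$noise_sd_pa > 0) {
    current <- current + rnorm(n, 0, channels$noise_sd_pa)
  }
  current <- filter_trace(current, protocol$filter_khz, protocol$sampling_khz)

  stim <- numeric(n)
  stim[onset:end_idx] <- pressure_mmhg

  t_on <- t_s[onset]
  t_off <- protocol$pre_s + protocol$step_duration_s
  open_in_window <- 0
  if (nrow(events)) {
    open_in_window <- sum(pmax(0, pmin(events$t_close, t_off) -
                                  pmax(events$t_open, t_on)))
  }

  new_sweep(time_s = t_s, current_pa = current, stimulus = stim,
            sampling_khz = protocol$sampling_khz,
            holding_mv = protocol$holding_mv,
            onset_index = onset, end_index = end_idx,
            meta = list(kind = "pressure", pressure_mmhg = pressure_mmhg,
                        truth = c(unclass(channels), list(
                          p_open = p_open(pressure_mmhg, channels),
                          unitary_pa = unitary_pa,
                          events = events,
                          n_open_events = nrow(events),
                          total_open_time_s = open_in_window))))
}

#' Simulate a pressure-step series with baseline sweeps
#'
#' One sweep per protocol pressure step plus `n_baseline` stimulus-free
#' sweeps (pressure 0) of the same duration, as required by the responder
#' criterion.
#'
#' @inheritParams simulate_pressure_sweep
#' @param n_baseline Number of stimulus-free baseline sweeps; the default of
#'   8 keeps the baseline charge SD well estimated for responder calling.
#' @return A list with elements `stimulus` (list of sweeps, one per pressure)
#'   and `baseline` (list of zero-pressure sweeps).
#' @export
simulate_pressure_series <- function(protocol, channels, seed = NULL,
                                     n_baseline = 8) {
  base <- if (is.null(seed)) NULL else as.integer(seed)
  stim <- lapply(seq_along(protocol$pressure_steps_mmhg), function(i) {
    s <- if (is.null(base)) NULL else base + i
    simulate_pressure_sweep(protocol, channels,
                            protocol$pressure_steps_mmhg[i], seed = s)
  })
  bl <- lapply(seq_len(n_baseline), function(i) {
    s <- if (is.null(base)) NULL else base + 1000L + i
    simulate_pressure_sweep(protocol, channels, 0, seed = s)
  })
  list(stimulus = stim, baseline = bl)
}
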