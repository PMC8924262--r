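# Shared fixtures: hand-built sweeps and scaled-down protocols.

# a plain sweep with given current trace; 20 ms pre-stimulus at 10 kHz unless
# overridden
make_test_sweep <- function(current_pa, sampling_khz = 10, pre_ms = 20,
                            stim_ms = 50, holding_mv = -60,
                            stimulus = NULL, meta = list()) {
  n <- length(current_pa)
  onset <- round(pre_ms * sampling_khz) + 1L
  end_idx <- min(n, onset + round(stim_ms * sampling_khz) - 1L)
  t_s <- (seq_len(n) - 1) / (sampling_khz * 1000)
  if (is.null(stimulus)) {
    stimulus <- numeric(n)
    stimulus[onset:end_idx] <- 1
  }
  new_sweep(t_s, current_pa, stimulus, sampling_khz = sampling_khz,
            holding_mv = holding_mv, onset_index = onset,
            end_index = end_idx, meta = meta)
}

# short pressure protocol for pipeline tests: enough stimulus for a 500-ms
# histogram segment, but far cheaper than the full 3-s step
short_pressure_protocol <- function(holding_mv = -100) {
  pressure_protocol(step_duration_s = 0.6, pre_s = 0.1, post_s = 0.05,
                    holding_mv = holding_mv)
}

# independent log-linear tau estimate on a noiseless decay segment
loglinear_tau_ms <- function(t_s, y) {
  keep <- abs(y) > 0.02 * max(abs(y))
  fit <- stats::lm(log(abs(y[keep])) ~ t_s[keep])
  -1000 / unname(stats::coef(fit)[2])
}
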