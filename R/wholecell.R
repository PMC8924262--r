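# Whole-cell poking-current analysis.
#
# Quantities extracted per sweep: leak-subtracted current, peak amplitude,
# onset latency / mechanical activation threshold (6-SD rule), inactivation
# time constant (single-exponential fit anchored at the peak), and per-series
# displacement-response curves, velocity-sensitivity ratios and reversal
# potential.

#' Subtract the leak current
#'
#' The constant leak is estimated as the mean of the baseline window (the
#' pre-stimulus segment minus its first 5 ms) and subtracted from the whole
#' trace, so the pre-stimulus mean of the returned sweep is exactly zero.
#'
#' @param sweep A [new_sweep()] with at least 10 ms of pre-stimulus data.
#' @return The leak-subtracted sweep; the subtracted constant is recorded in
#'   `sweep_meta(.)$leak_subtracted_pa`.
#' @export
subtract_leak <- function(sweep) {
  idx <- baseline_indices(sweep)
  leak <- mean(sweep$current_pa[idx])
  out <- sweep
  out$current_pa <- sweep$current_pa - leak
  set_sweep_meta(out, leak_subtracted_pa = leak, leak_subtracted = TRUE)
}

#' Peak current within a window
#'
#' The signed current at the extremum of largest magnitude inside `window`.
#' By default the search window runs from stimulus onset to 5 ms past the
#' stimulus end, which avoids off-stimulus artifacts.
#'
#' @param sweep A leak-subtracted sweep.
#' @param window Integer sample range (two-element vector) to search; `NULL`
#'   for the default.
#' @return Signed peak current in pA (negative = inward).
#' @export
peak_current <- function(sweep, window = NULL) {
  fs <- sweep_attr(sweep, "sampling_khz")
  if (is.null(window)) {
    window <- c(sweep_attr(sweep, "onset_index"),
                min(nrow(sweep), sweep_attr(sweep, "end_index") + round(5 * fs)))
  }
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be a non-empty sample range c(from, to).")
  }
  idx <- seq.int(max(1L, window[1]), min(nrow(sweep), window[2]))
  if (!length(idx)) abort("`window` is empty.")
  x <- sweep$current_pa[idx]
  x[which.max(abs(x))]
}

#' Detect current onset and the mechanical activation threshold
#'
#' The onset is the first sample at or after stimulus onset where the current
#' crosses `baseline_mean - k_sd * baseline_sd` (inward convention; the
#' crossing side flips for outward currents at positive holding potentials).
#' The characterized group delay of the acquisition filter is subtracted from
#' the latency, and the threshold displacement is `latency * ramp_speed`,
#' clamped at the ramp amplitude when the onset falls in the hold phase.
#'
#' @param sweep A leak-subtracted sweep.
#' @param ramp_speed_um_ms Probe velocity (um/ms).
#' @param k_sd Number of baseline SDs defining a significant deflection.
#' @param min_sd Floor for the baseline SD (pA); the default 0 errors on a
#'   degenerate (zero-variance) baseline, a positive floor permits onset
#'   detection on noiseless synthetic sweeps.
#' @param direction `"auto"` (inward for negative holding potentials),
#'   `"inward"` or `"outward"`.
#' @return A one-row tibble: `detected`, `latency_ms`, `threshold_um`,
#'   `baseline_mean_pa`, `baseline_sd_pa`.
#' @export
detect_onset <- function(sweep, ramp_speed_um_ms = 1, k_sd = 6, min_sd = 0,
                         direction = c("auto", "inward", "outward")) {
  direction <- match.arg(direction)
  fs <- sweep_attr(sweep, "sampling_khz")
  onset_idx <- sweep_attr(sweep, "onset_index")
  end_idx <- sweep_attr(sweep, "end_index")
  bl <- baseline_stats(sweep)
  sd_eff <- max(bl$sd, min_sd)
  if (sd_eff == 0 && k_sd > 0) {
    abort("degenerate baseline: SD is 0; supply a positive `min_sd`.")
  }
  if (direction == "auto") {
    direction <- if (sweep_attr(sweep, "holding_mv") < 0) "inward" else "outward"
  }
  seg <- sweep$current_pa[onset_idx:end_idx]
  crossed <- if (direction == "inward") {
    seg < bl$mean - k_sd * sd_eff
  } else {
    seg > bl$mean + k_sd * sd_eff
  }
  hit <- which(crossed)[1]
  meta <- sweep_meta(sweep)
  amp <- meta$amplitude_um %||% max(sweep$stimulus)
  if (is.na(hit)) {
    return(tibble(detected = FALSE, latency_ms = NA_real_,
                  threshold_um = NA_real_, baseline_mean_pa = bl$mean,
                  baseline_sd_pa = bl$sd))
  }
  delay <- filter_delay_ms(sweep_filter_khz(sweep), fs)
  latency <- max(0, (hit - 1) / fs - delay)
  thr <- min(latency * ramp_speed_um_ms, amp)
  tibble(detected = TRUE, latency_ms = latency, threshold_um = thr,
         baseline_mean_pa = bl$mean, baseline_sd_pa = bl$sd)
}

# cutoff used when the sweep was acquired; falls back to the standard 2.9 kHz
sweep_filter_khz <- function(sweep) {
  sweep_meta(sweep)$filter_khz %||% 2.9
}

#' Fit the inactivation time constant
#'
#' Least-squares fit of `C1 + C2 * exp(-(t - t0) / tau)` to the decay phase,
#' with `t0` fixed at the peak time (this makes C1 and C2 identifiable).
#'
#' @param sweep A leak-subtracted sweep.
#' @param fit_window Integer sample range; defaults to peak sample through
#'   stimulus end.
#' @return An object of class `pq_inact_fit` with elements `c1_pa`, `c2_pa`,
#'   `t0_s`, `tau_inact_ms`, `rss`, `converged`; see [tidy()] / [glance()].
#' @export
fit_inactivation <- function(sweep, fit_window = NULL) {
  fs <- sweep_attr(sweep, "sampling_khz")
  end_idx <- sweep_attr(sweep, "end_index")
  bl <- baseline_stats(sweep)
  if (is.null(fit_window)) {
    pk_win <- c(sweep_attr(sweep, "onset_index"), end_idx)
    seg <- sweep$current_pa[pk_win[1]:pk_win[2]]
    pk <- pk_win[1] + which.max(abs(seg)) - 1L
    fit_window <- c(pk, end_idx)
  }
  idx <- seq.int(fit_window[1], fit_window[2])
  if (length(idx) < 20) abort("fit window must contain at least 20 samples.")
  y <- sweep$current_pa[idx]
  if (bl$sd > 0 && abs(y[1]) <= 5 * bl$sd) {
    abort("peak magnitude must exceed 5x the baseline SD.")
  }
  t0 <- sweep$time_s[idx[1]]
  tt <- sweep$time_s[idx] - t0

  c1_0 <- mean(tail(y, max(5L, length(y) %/% 20)))
  c2_0 <- y[1] - c1_0
  if (abs(c2_0) <= max(2 * bl$sd, 1e-9 * max(1, abs(y[1])))) {
    abort("no decay component")
  }
  # log-linear starting value for tau, on the early decay only (the tail is
  # dominated by filter ripple once the exponential has died away)
  resid0 <- (y - c1_0) / c2_0
  ok <- which(resid0 > 0.05)
  win <- tt[length(tt)] - tt[1]
  tau0 <- if (length(ok) >= 5) {
    -1 / coef(lm(log(resid0[ok]) ~ tt[ok]))[2]
  } else {
    win / 5
  }
  if (!is.finite(tau0)) tau0 <- win / 5
  tau0 <- min(max(tau0, 2 / (fs * 1000)), 2 * win)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ c1 + c2 * exp(-tt / tau),
                      start = list(c1 = c1_0, c2 = c2_0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(c1_pa = NA_real_, c2_pa = NA_real_, t0_s = t0,
                tau_inact_ms = NA_real_, rss = NA_real_, converged = FALSE)
  } else {
    cf <- coef(fit)
    out <- list(c1_pa = unname(cf["c1"]), c2_pa = unname(cf["c2"]), t0_s = t0,
                tau_inact_ms = unname(cf["tau"]) * 1000,
                rss = sum(stats::resid(fit)^2), converged = TRUE)
    if (out$tau_inact_ms <= 0) out$converged <- FALSE
  }
  structure(out, class = "pq_inact_fit")
}

#' @export
print.pq_inact_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<pq_inact_fit> tau_inact = %.3f ms (C1 = %.1f pA, C2 = %.1f pA)\n",
                x$tau_inact_ms, x$c1_pa, x$c2_pa))
  } else {
    cat("<pq_inact_fit> did not converge\n")
  }
  invisible(x)
}

#' Displacement-response curve of a poking series
#'
#' One point per sweep: commanded displacement vs peak current magnitude.
#' Sweeps flagged as excluded (QC) are omitted, mirroring variable N per
#' displacement in real data sets.
#'
#' @param sweeps List of leak-subtracted sweeps from one cell, in step order.
#' @return A tibble of class `pq_drc` with columns `displacement_um`,
#'   `peak_pa` (magnitude), `responded` (peak above 6x baseline SD).
#' @export
displacement_response <- function(sweeps) {
  if (!length(sweeps)) abort("`sweeps` is empty.")
  rows <- purrr::map(sweeps, function(sw) {
    if (isTRUE(sweep_meta(sw)$excluded)) return(NULL)
    bl <- baseline_stats(sw)
    pk <- peak_current(sw)
    tibble(displacement_um = sweep_meta(sw)$amplitude_um %||% max(sw$stimulus),
           peak_pa = abs(pk),
           responded = abs(pk) > 6 * bl$sd)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$displacement_um)
  if (any(duplicated(out$displacement_um))) {
    abort("duplicate displacements; pass one sweep per step.")
  }
  class(out) <- c("pq_drc", class(out))
  out
}

#' Velocity-sensitivity ratio with stability QC
#'
#' Computes the ratio of mean test-velocity amplitude to mean
#' reference-velocity amplitude. A cell is excluded when the coefficient of
#' variation of its last three reference responses exceeds 0.2.
#'
#' @param amplitudes A tibble with columns `velocity_um_ms` and
#'   `amplitude_pa` (peak magnitudes), rows in recording order; at least three
#'   reference-velocity rows must precede the test rows.
#' @param reference_velocity,test_velocity Velocities (um/ms) defining the
#'   ratio, default `I(0.25)/I(1)`.
#' @return A one-row tibble: `ratio`, `stability_cv`, `excluded`,
#'   `mean_reference_pa`, `mean_test_pa`.
#' @export
velocity_ratio <- function(amplitudes, reference_velocity = 1,
                           test_velocity = 0.25) {
  stopifnot(is.data.frame(amplitudes),
            all(c("velocity_um_ms", "amplitude_pa") %in% names(amplitudes)))
  ref <- amplitudes$amplitude_pa[amplitudes$velocity_um_ms == reference_velocity]
  tst <- amplitudes$amplitude_pa[amplitudes$velocity_um_ms == test_velocity]
  if (length(ref) < 3) {
    abort("need at least 3 reference-velocity amplitudes.")
  }
  if (!length(tst)) abort("no amplitudes at the test velocity.")
  last3 <- tail(ref, 3)
  cv <- sd(last3) / mean(last3)
  tibble(ratio = mean(tst) / mean(ref),
         stability_cv = cv,
         excluded = cv > 0.2,
         mean_reference_pa = mean(ref),
         mean_test_pa = mean(tst))
}

#' Reversal potential from an I/V series
#'
#' Zero crossing of the linear interpolation between the sign-change pair of
#' the I/V relation; when no sign change exists the least-squares line is
#' extrapolated and the result flagged.
#'
#' @param iv A tibble with columns `voltage_mv` and `peak_pa` (signed peaks),
#'   e.g. from -60 to +60 mV in 30 mV steps.
#' @return A one-row tibble: `e_rev_mv`, `extrapolated`.
#' @export
reversal_potential <- function(iv) {
  stopifnot(is.data.frame(iv), all(c("voltage_mv", "peak_pa") %in% names(iv)))
  iv <- dplyr::arrange(iv, .data$voltage_mv)
  if (nrow(iv) < 2) abort("need at least 2 holding potentials.")
  v <- iv$voltage_mv; i <- iv$peak_pa
  if (any(i == 0)) {
    return(tibble(e_rev_mv = v[which(i == 0)[1]], extrapolated = FALSE))
  }
  sgn <- which(diff(sign(i)) != 0)
  if (length(sgn)) {
    k <- sgn[1]
    e <- v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
    tibble(e_rev_mv = e, extrapolated = FALSE)
  } else {
    cf <- coef(lm(i ~ v))
    tibble(e_rev_mv = -cf[[1]] / cf[[2]], extrapolated = TRUE)
  }
}
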