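# Cell-attached pressure-clamp analysis.
#
# Stretch-evoked responses frequently fail to inactivate, which makes a peak
# current ill-defined; the stimulus-response quantity used here is therefore
# the total charge transferred during the pressure step (trapezoidal area
# under the curve, in pC). Single-channel properties come from two-Gaussian
# fits of amplitude histograms over 500-ms segments and a per-cell I/V
# regression.

#' Charge transferred during the pressure stimulus
#'
#' Trapezoidal integral of the leak-subtracted current over the stimulus
#' window; pA integrated over seconds gives pC directly. Reported as a
#' magnitude (inward responses); the signed value is kept alongside.
#'
#' @param sweep A leak-subtracted pressure sweep.
#' @param window Two-element numeric vector of times (s); defaults to the
#'   sweep's stimulus window.
#' @return One-row tibble: `pressure_mmhg`, `charge_pc` (magnitude),
#'   `charge_signed_pc`, `window_start_s`, `window_end_s`.
#' @export
charge_transfer <- function(sweep, window = NULL) {
  if (is.null(window)) {
    window <- sweep$time_s[c(sweep_attr(sweep, "onset_index"),
                             sweep_attr(sweep, "end_index"))]
  }
  tr <- range(sweep$time_s)
  if (window[1] < tr[1] - 1e-12 || window[2] > tr[2] + 1e-12 ||
      window[1] >= window[2]) {
    abort("`window` must be an increasing time range inside the sweep.")
  }
  idx <- which(sweep$time_s >= window[1] & sweep$time_s <= window[2])
  t <- sweep$time_s[idx]; y <- sweep$current_pa[idx]
  q <- sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  tibble(pressure_mmhg = sweep_meta(sweep)$pressure_mmhg %||% min(sweep$stimulus),
         charge_pc = abs(q), charge_signed_pc = q,
         window_start_s = window[1], window_end_s = window[2])
}

# default histogram bin width: max(0.1 pA, 2 * noise_sd / 5), noise_sd
# estimated robustly from the first difference of the segment
default_bin_width <- function(y) {
  noise_sd <- mad(diff(y)) / sqrt(2)
  max(0.1, 2 * noise_sd / 5)
}

# local maxima of histogram counts, ordered by height
histogram_modes <- function(mids, counts) {
  n <- length(counts)
  if (n < 3) return(integer())
  is_max <- counts > c(-Inf, counts[-n]) & counts >= c(counts[-1], -Inf)
  idx <- which(is_max & counts > 0)
  idx[order(counts[idx], decreasing = TRUE)]
}

#' Amplitude histogram with two-Gaussian fit
#'
#' Builds the all-points amplitude histogram of a segment (default 500 ms)
#' and fits a two-component Gaussian to the binned counts. The unitary
#' current is the absolute difference between the two fitted peaks. The fit
#' is initialized from the two largest histogram modes, ties broken toward
#' the mode nearer 0 pA as the closed level.
#'
#' @param sweep A pressure sweep (leak-subtracted or not: the unitary current
#'   is invariant to a constant offset).
#' @param segment_start_s Start of the analysis segment (s); defaults to the
#'   stimulus onset.
#' @param segment_s Segment duration (s).
#' @param bin_width_pa Histogram bin width (pA); default
#'   `max(0.1, 2 * noise_sd / 5)` with the noise SD estimated robustly.
#' @return An object of class `pq_amp_hist`: `bin_mids_pa`, `counts`,
#'   `components` (tibble mean/sd/weight), `unitary_pa`, `segment_s`.
#' @export
amplitude_histogram <- function(sweep, segment_start_s = NULL,
                                segment_s = 0.5, bin_width_pa = NULL) {
  if (is.null(segment_start_s)) {
    segment_start_s <- sweep$time_s[sweep_attr(sweep, "onset_index")]
  }
  t1 <- segment_start_s + segment_s
  if (segment_start_s < sweep$time_s[1] - 1e-12 ||
      t1 > tail(sweep$time_s, 1) + 1e-12) {
    abort("segment lies outside the sweep.")
  }
  y <- sweep$current_pa[sweep$time_s >= segment_start_s & sweep$time_s < t1]
  bw <- bin_width_pa %||% default_bin_width(y)
  breaks <- seq(min(y) - bw, max(y) + bw, by = bw)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  ntot <- sum(counts)

  modes <- histogram_modes(mids, counts)
  if (length(modes) < 2) {
    # fall back: second component seeded one robust SD away from the mode
    modes <- c(modes[1], which.min(abs(mids - (mids[modes[1]] - 5 * bw))))
  }
  m1 <- mids[modes[1]]; m2 <- mids[modes[2]]
  # closed level = mode nearer 0 pA
  if (abs(m2) < abs(m1)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  s0 <- max(bw, mad(y) / 2)
  w0 <- min(0.9, max(0.1, sum(counts[abs(mids - m1) < abs(m1 - m2) / 2]) / ntot))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ ntot * bw * (w * dnorm(mids, mu1, s1) +
                              (1 - w) * dnorm(mids, mu2, s2)),
      start = list(mu1 = m1, mu2 = m2, s1 = s0, s2 = s0, w = w0),
      lower = c(-Inf, -Inf, bw / 10, bw / 10, 1e-4),
      upper = c(Inf, Inf, Inf, Inf, 1 - 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # quasi-discrete segments (e.g. noiseless two-level traces) are singular
    # for a continuous mixture fit; fall back to a two-cluster split at the
    # midpoint between the modes
    cut <- (m1 + m2) / 2
    side <- if (m2 < m1) y < cut else y >= cut
    if (sum(side) < 2 || sum(!side) < 2) abort("no resolvable openings")
    cf <- c(mu1 = mean(y[!side]), mu2 = mean(y[side]),
            s1 = max(sd(y[!side]), bw / 10), s2 = max(sd(y[side]), bw / 10),
            w = mean(!side))
  } else {
    cf <- coef(fit)
  }
  w <- unname(cf["w"])
  sep <- abs(cf["mu2"] - cf["mu1"])
  pooled <- sqrt(w * cf["s1"]^2 + (1 - w) * cf["s2"]^2)
  # compare against a single-Gaussian fit: if the second component does not
  # substantially reduce the residual, the histogram has one effective level
  one_level <- FALSE
  if (!is.null(fit)) {
    fit1 <- tryCatch(
      minpack.lm::nlsLM(counts ~ ntot * bw * dnorm(mids, mu, s),
                        start = list(mu = mean(y), s = max(s0, sd(y))),
                        lower = c(-Inf, bw / 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    rss2 <- sum(stats::resid(fit)^2)
    rss1 <- if (is.null(fit1)) Inf else sum(stats::resid(fit1)^2)
    one_level <- is.finite(rss1) && rss2 > 0.8 * rss1
  }
  # openings are resolvable only when the level separation exceeds the level
  # widths themselves as well as the counting uncertainty
  if (min(w, 1 - w) < 0.02 || sep < 2 * pooled / sqrt(ntot) ||
      sep < 2 * pooled || one_level) {
    abort("no resolvable openings")
  }
  comps <- tibble(mean_pa = c(unname(cf["mu1"]), unname(cf["mu2"])),
                  sd_pa = c(unname(cf["s1"]), unname(cf["s2"])),
                  weight = c(w, 1 - w),
                  level = c("closed", "open"))
  structure(list(bin_mids_pa = mids, counts = counts, bin_width_pa = bw,
                 components = comps, unitary_pa = unname(sep),
                 segment_s = segment_s, n_samples = ntot),
            class = "pq_amp_hist")
}

#' @export
print.pq_amp_hist <- function(x, ...) {
  cat(sprintf("<pq_amp_hist> unitary current %.3f pA (%d samples, %.0f ms segment)\n",
              x$unitary_pa, x$n_samples, x$segment_s * 1000))
  invisible(x)
}

#' Unitary conductance from a per-cell I/V regression
#'
#' Ordinary least-squares regression of signed unitary currents on holding
#' potential; the slope in pA/mV times 1000 is the conductance in pS.
#'
#' @param iv A tibble with columns `voltage_mv` and `unitary_pa` (signed:
#'   negative for inward current at negative potentials), one row per holding
#'   potential for one cell; at least 3 points.
#' @return An object of class `pq_conductance_fit`: `slope_ps`,
#'   `intercept_pa`, `r_squared`, `reversal_mv`, and the underlying `lm` fit.
#' @export
unitary_conductance <- function(iv) {
  stopifnot(is.data.frame(iv),
            all(c("voltage_mv", "unitary_pa") %in% names(iv)))
  iv <- iv[complete.cases(iv[c("voltage_mv", "unitary_pa")]), ]
  if (nrow(iv) < 3) abort("need unitary currents at >= 3 holding potentials.")
  fit <- lm(unitary_pa ~ voltage_mv, data = iv)
  cf <- coef(fit)
  tss <- sum((iv$unitary_pa - mean(iv$unitary_pa))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  structure(list(slope_ps = unname(cf[2]) * 1000,
                 intercept_pa = unname(cf[1]),
                 r_squared = r2,
                 reversal_mv = -unname(cf[1]) / unname(cf[2]),
                 n = nrow(iv), fit = fit),
            class = "pq_conductance_fit")
}

#' @export
print.pq_conductance_fit <- function(x, ...) {
  cat(sprintf("<pq_conductance_fit> g = %.2f pS (r^2 = %.3f, n = %d)\n",
              x$slope_ps, x$r_squared, x$n))
  invisible(x)
}

#' Responder call for one cell
#'
#' A cell responds when the charge transferred at any tested pressure exceeds
#' 5 times the SD of charges measured on stimulus-free baseline segments of
#' equal duration. The SD is taken over the signed baseline charges (a
#' zero-mean quantity), which keeps the criterion calibrated; the response
#' charges are compared as magnitudes.
#'
#' @param stimulus_sweeps List of leak-subtracted sweeps, one per pressure.
#' @param baseline_sweeps List of at least two stimulus-free sweeps of the
#'   same stimulus-window duration.
#' @param k_sd Multiplier on the baseline charge SD.
#' @return One-row tibble: `responded`, `max_charge_pc`,
#'   `criterion_threshold_pc`, `pressures_tested` (list-column).
#' @export
classify_responder <- function(stimulus_sweeps, baseline_sweeps, k_sd = 5) {
  if (!length(baseline_sweeps)) abort("at least one baseline sweep is required.")
  if (length(baseline_sweeps) < 2) {
    abort("baseline charge SD needs >= 2 stimulus-free sweeps.")
  }
  bq <- purrr::map_dbl(baseline_sweeps, ~ charge_transfer(.x)$charge_signed_pc)
  sq <- purrr::map_dfr(stimulus_sweeps, charge_transfer)
  thr <- k_sd * sd(bq)
  tibble(responded = any(sq$charge_pc > thr),
         max_charge_pc = max(sq$charge_pc),
         criterion_threshold_pc = thr,
         pressures_tested = list(sq$pressure_mmhg))
}

#' Patch quality control
#'
#' A recording is excluded when the pre-stimulus leak exceeds 4 pA in
#' magnitude (strict inequality) or the baseline drifts faster than the slope
#' bound.
#'
#' @param sweep A pressure sweep (raw, not leak-subtracted).
#' @param max_leak_pa Leak magnitude bound (pA).
#' @param max_drift_pa_s Baseline linear-drift bound (pA/s).
#' @return One-row tibble: `excluded`, `leak_pa`, `drift_pa_s`, `reason`.
#' @export
qc_patch <- function(sweep, max_leak_pa = 4, max_drift_pa_s = 2) {
  idx <- baseline_indices(sweep)
  y <- sweep$current_pa[idx]; t <- sweep$time_s[idx]
  leak <- mean(y)
  drift <- unname(coef(lm(y ~ t))[2])
  reasons <- c(
    if (abs(leak) > max_leak_pa) sprintf("leak %.2f pA > %g pA", abs(leak), max_leak_pa),
    if (abs(drift) > max_drift_pa_s) sprintf("drift %.2f pA/s > %g pA/s", abs(drift), max_drift_pa_s))
  tibble(excluded = length(reasons) > 0, leak_pa = leak, drift_pa_s = drift,
         reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_)
}
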