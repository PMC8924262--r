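# Sweep container: the universal electrophysiology record.
#
# A sweep is a tibble with one row per sample (columns `time_s`, `current_pa`,
# `stimulus`) plus acquisition metadata carried as attributes. The stimulus
# column is membrane displacement (um) for poking sweeps and applied pressure
# (mmHg) for pressure-clamp sweeps. Ground-truth generative parameters, when
# the sweep is synthetic, live in `meta$truth` and are read only by recovery
# tests, never by the analysis code.

#' Construct a sweep
#'
#' @param time_s Strictly increasing, uniformly spaced time base in seconds.
#' @param current_pa Current trace in pA (inward negative).
#' @param stimulus Stimulus trace (displacement in um or pressure in mmHg).
#' @param sampling_khz Sampling rate in kHz.
#' @param holding_mv Holding potential in mV.
#' @param onset_index,end_index Sample indices (1-based) of stimulus onset and
#'   stimulus end.
#' @param meta Free-form list of metadata; synthetic sweeps store their
#'   generative ground truth under `meta$truth`.
#' @return A tibble of class `pq_sweep`.
#' @export
new_sweep <- function(time_s, current_pa, stimulus, sampling_khz, holding_mv,
                      onset_index, end_index, meta = list()) {
  n <- length(time_s)
  if (length(current_pa) != n || length(stimulus) != n) {
    abort("`time_s`, `current_pa` and `stimulus` must have equal length.")
  }
  if (n >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt) + 1e-15) {
      abort("`time_s` must be strictly increasing and uniformly spaced.")
    }
  }
  onset_index <- as.integer(onset_index)
  end_index <- as.integer(end_index)
  if (!(onset_index >= 1 && onset_index < end_index && end_index <= n)) {
    abort("need 1 <= onset_index < end_index <= length(time_s).")
  }
  out <- tibble(time_s = as.numeric(time_s),
                current_pa = as.numeric(current_pa),
                stimulus = as.numeric(stimulus))
  attr(out, "sampling_khz") <- sampling_khz
  attr(out, "holding_mv") <- holding_mv
  attr(out, "onset_index") <- onset_index
  attr(out, "end_index") <- end_index
  attr(out, "meta") <- meta
  class(out) <- c("pq_sweep", class(out))
  out
}

#' @export
print.pq_sweep <- function(x, ...) {
  cat(sprintf("<pq_sweep> %d samples @ %g kHz, holding %g mV, stimulus window [%d, %d]\n",
              nrow(x), attr(x, "sampling_khz"), attr(x, "holding_mv"),
              attr(x, "onset_index"), attr(x, "end_index")))
  NextMethod()
}

sweep_attr <- function(sweep, what) {
  v <- attr(sweep, what, exact = TRUE)
  if (is.null(v)) abort(sprintf("sweep is missing attribute `%s`.", what))
  v
}

#' Access sweep metadata
#' @param sweep A `pq_sweep`.
#' @return The metadata list.
#' @export
sweep_meta <- function(sweep) attr(sweep, "meta", exact = TRUE) %||% list()

set_sweep_meta <- function(sweep, ...) {
  m <- sweep_meta(sweep)
  new <- list(...)
  m[names(new)] <- new
  attr(sweep, "meta") <- m
  sweep
}

# indices of the baseline window: the pre-stimulus segment minus its first
# 5 ms (settling). Errors if fewer than `min_ms` of pre-stimulus data exist.
baseline_indices <- function(sweep, min_ms = 10, skip_ms = 5) {
  fs <- sweep_attr(sweep, "sampling_khz")
  onset <- sweep_attr(sweep, "onset_index")
  pre_ms <- (onset - 1) / fs
  if (pre_ms < min_ms) {
    abort(sprintf(
      "pre-stimulus window is %.2f ms; at least %g ms are required.",
      pre_ms, min_ms))
  }
  from <- floor(skip_ms * fs) + 1L
  seq.int(from, onset - 1L)
}

baseline_stats <- function(sweep) {
  idx <- baseline_indices(sweep)
  x <- sweep$current_pa[idx]
  list(mean = mean(x), sd = sd(x), n = length(x))
}
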