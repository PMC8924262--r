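# broom-style tidiers for the package's fitted objects.

#' @rdname pq_tidiers
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy pq_inact_fit
#' @export
tidy.pq_inact_fit <- function(x, ...) {
  tibble(term = c("c1_pa", "c2_pa", "tau_inact_ms"),
         estimate = c(x$c1_pa, x$c2_pa, x$tau_inact_ms))
}

#' @rdname pq_tidiers
#' @method glance pq_inact_fit
#' @export
glance.pq_inact_fit <- function(x, ...) {
  tibble(tau_inact_ms = x$tau_inact_ms, rss = x$rss, converged = x$converged)
}

#' Tidiers for piezoquant fit objects
#'
#' [tidy()] returns one row per model term; [glance()] returns a one-row
#' model summary.
#'
#' @name pq_tidiers
#' @rdname pq_tidiers
#' @method tidy pq_amp_hist
#' @export
tidy.pq_amp_hist <- function(x, ...) {
  out <- x$components
  out$term <- out$level
  out[c("term", "mean_pa", "sd_pa", "weight")]
}

#' @rdname pq_tidiers
#' @method glance pq_amp_hist
#' @export
glance.pq_amp_hist <- function(x, ...) {
  tibble(unitary_pa = x$unitary_pa, n_samples = x$n_samples,
         segment_s = x$segment_s)
}

#' @rdname pq_tidiers
#' @method tidy pq_conductance_fit
#' @export
tidy.pq_conductance_fit <- function(x, ...) {
  tibble(term = c("intercept_pa", "slope_ps"),
         estimate = c(x$intercept_pa, x$slope_ps))
}

#' @rdname pq_tidiers
#' @method glance pq_conductance_fit
#' @export
glance.pq_conductance_fit <- function(x, ...) {
  tibble(slope_ps = x$slope_ps, r_squared = x$r_squared,
         reversal_mv = x$reversal_mv, n = x$n)
}
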