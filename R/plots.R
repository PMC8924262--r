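# ggplot2 visualisations for the main result types.

#' @rdname pq_plots
#' @param object Object to plot.
#' @param ... Unused.
#' @method autoplot pq_sweep
#' @export
autoplot.pq_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("current_pa", "stimulus"),
                            names_to = "channel", values_to = "value")
  df$channel <- factor(df$channel, c("stimulus", "current_pa"),
                       c("stimulus", "current (pA)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plots for piezoquant result objects
#'
#' `autoplot()` methods for sweeps, displacement-response curves, amplitude
#' histograms and MSD curves.
#'
#' @name pq_plots
#' @rdname pq_plots
#' @method autoplot pq_drc
#' @export
autoplot.pq_drc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$displacement_um, .data$peak_pa)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$responded)) +
    ggplot2::labs(x = "displacement (µm)", y = "peak current (pA)") +
    ggplot2::theme_minimal()
}

#' @rdname pq_plots
#' @method autoplot pq_amp_hist
#' @export
autoplot.pq_amp_hist <- function(object, ...) {
  df <- tibble(mid = object$bin_mids_pa, count = object$counts)
  ntot <- object$n_samples; bw <- object$bin_width_pa
  grid <- seq(min(df$mid), max(df$mid), length.out = 400)
  comp <- object$components
  fit <- tibble(
    mid = grid,
    count = ntot * bw * (comp$weight[1] * dnorm(grid, comp$mean_pa[1], comp$sd_pa[1]) +
                           comp$weight[2] * dnorm(grid, comp$mean_pa[2], comp$sd_pa[2])))
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = bw, fill = "grey70") +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::labs(x = "current (pA)", y = "samples") +
    ggplot2::theme_minimal()
}

#' @rdname pq_plots
#' @method autoplot pq_msd
#' @export
autoplot.pq_msd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (s)", y = "MSD (µm²)") +
    ggplot2::theme_minimal()
}
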