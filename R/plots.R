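# ggplot2 graphics for simulations and analyses.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_tile labs facet_wrap scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Raster plot of a simulation
#'
#' @param x An `stngpe_sim` or spikes tibble.
#' @param populations Populations to show.
#' @param t_range Optional time range (ms).
#' @return A ggplot.
#' @export
plot_raster <- function(x, populations = c("STN", "GPe"), t_range = NULL) {
  spikes <- if (inherits(x, "stngpe_sim")) x$spikes else x
  spikes <- filter(spikes, .data$population %in% populations)
  if (!is.null(t_range))
    spikes <- filter(spikes, .data$time_ms >= t_range[1],
                     .data$time_ms <= t_range[2])
  ggplot(spikes, aes(x = .data$time_ms, y = .data$neuron)) +
    geom_point(shape = "|", size = 1.2) +
    facet_wrap(~ .data$population, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = "neuron") +
    theme_minimal()
}

#' @rdname plot_raster
#' @param object An `stngpe_sim`.
#' @param ... Passed to [plot_raster()].
#' @export
autoplot.stngpe_sim <- function(object, ...) plot_raster(object, ...)

#' Compensated-spectrum plot with confidence level
#'
#' @param object A [compensated_psd()] or [compensated_csd()] result.
#' @param f_max Upper frequency limit (Hz).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stngpe_psd <- function(object, f_max = 50, ...) {
  lev <- attr(object, "confidence_level")
  df <- filter(tibble(frequency = object$frequency,
                      density = object$density),
               .data$frequency <= f_max)
  ggplot(df, aes(x = .data$frequency, y = .data$density)) +
    geom_line() +
    geom_hline(yintercept = lev, linetype = "dashed", colour = "red") +
    labs(x = "frequency (Hz)", y = "compensated density") +
    theme_minimal()
}

#' @rdname autoplot.stngpe_psd
#' @export
autoplot.stngpe_csd <- autoplot.stngpe_psd

#' Conductance-plane sweep map
#'
#' @param object A [run_sweep()] result.
#' @param metric Summary column to map.
#' @param population Population to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stngpe_sweep <- function(object, metric = "peak_power_mean",
                                  population = "STN", ...) {
  df <- filter(object, .data$population == !!population)
  ggplot(df, aes(x = .data$g_gaba_gpe_stn, y = .data$g_ampa_gpe_int,
                 fill = .data[[metric]])) +
    geom_tile() +
    labs(x = "GPe->STN conductance (nS)",
         y = "GPe intrinsic conductance (nS)", fill = metric) +
    theme_minimal()
}
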