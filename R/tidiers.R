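# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a compensated power spectrum
#'
#' @param x A [compensated_psd()] result.
#' @param ... Unused.
#' @return Tibble with `frequency`, `density`, and logical `significant`.
#' @export
tidy.stngpe_psd <- function(x, ...) {
  tibble(frequency = x$frequency, density = x$density,
         significant = x$density > attr(x, "confidence_level"))
}

#' @rdname tidy.stngpe_psd
#' @export
tidy.stngpe_csd <- function(x, ...) {
  tibble(frequency = x$frequency, density = x$density,
         phase_deg = x$phase_deg,
         significant = x$density > attr(x, "confidence_level"))
}

#' One-row summary of a compensated spectrum
#'
#' @param x A [compensated_psd()] or [compensated_csd()] result.
#' @param ... Unused.
#' @return One-row tibble: confidence level, classification flag, band
#'   peak density and its frequency, spike count.
#' @export
glance.stngpe_psd <- function(x, ...) {
  band <- attr(x, "band")
  inb <- x$frequency >= band[1] & x$frequency <= band[2]
  tibble(confidence_level = attr(x, "confidence_level"),
         oscillatory = isTRUE(attr(x, "oscillatory")),
         peak_density = max(x$density[inb]),
         peak_frequency = x$frequency[inb][which.max(x$density[inb])],
         n_spikes = attr(x, "n_spikes"))
}

#' @rdname glance.stngpe_psd
#' @export
glance.stngpe_csd <- function(x, ...) {
  band <- attr(x, "band")
  inb <- x$frequency >= band[1] & x$frequency <= band[2]
  tibble(confidence_level = attr(x, "confidence_level"),
         correlated = isTRUE(attr(x, "correlated")),
         peak_density = max(x$density[inb]),
         peak_frequency = x$frequency[inb][which.max(x$density[inb])])
}

#' Tidy a state-point result
#'
#' @param x A [run_state_point()] result.
#' @param ... Unused.
#' @return The pooled per-neuron metrics tibble.
#' @export
tidy.stngpe_state_result <- function(x, ...) x$metrics

#' @rdname tidy.stngpe_state_result
#' @return For `glance()`, the per-population summary with the state label.
#' @export
glance.stngpe_state_result <- function(x, ...) {
  mutate(x$summary, label = x$point$label)
}
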