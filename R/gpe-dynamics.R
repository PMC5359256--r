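# Leaky integrate-and-fire dynamics of GPe model neurons.

#' Advance a GPe neuron by one time step
#'
#' Exact exponential subthreshold update of the conductance-based
#' integrate-and-fire membrane under a piecewise-constant total excitatory
#' conductance. On threshold crossing the membrane is reset and held for the
#' absolute refractory period, during which no spikes are emitted.
#'
#' @param state List with `v` (mV) and `refractory_left` (ms).
#' @param dt Time step (ms).
#' @param g_total Total excitatory conductance (nS) during the step.
#' @param params GPe parameters from [gpe_params()].
#' @return A list with the advanced `state` and logical `spike`.
#' @export
advance_gpe <- function(state, dt, g_total = 0, params = gpe_params()) {
  if (dt <= 0) abort("dt must be > 0")
  if (!is.finite(g_total) || g_total < 0)
    abort("g_total must be finite and >= 0")
  p <- params
  spike <- FALSE
  active <- state$refractory_left <= 0
  if (!active) {
    state$refractory_left <- state$refractory_left - dt
    if (state$refractory_left <= 1e-12) {
      state$refractory_left <- 0
      active <- TRUE
    }
  }
  if (active) {
    gtot <- p$g_leak + g_total
    vinf <- (p$g_leak * p$v_leak + g_total * p$v_exc) / gtot
    # cm in nF, g in nS, dt in ms: tau_ms = 1000 * cm / gtot
    state$v <- vinf + (state$v - vinf) * exp(-gtot * dt / (1000 * p$cm))
    if (state$v >= p$threshold) {
      spike <- TRUE
      state$v <- p$reset
      state$refractory_left <- p$refractory
    }
  }
  list(state = state, spike = spike)
}

#' Integrate a single GPe neuron trajectory
#'
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param g_exc Excitatory conductance (nS); scalar or per-step vector.
#' @param v0 Initial membrane potential (mV).
#' @param params GPe parameters.
#' @return Tibble with `time_ms`, `v`; attributes `spike_times`, `rate_hz`.
#' @export
gpe_trajectory <- function(duration, dt = 0.1, g_exc = 0, v0 = -70,
                           params = gpe_params()) {
  n <- round(duration / dt)
  res <- cpp_gpe_trajectory(params$cm, params$g_leak, params$v_leak,
                            params$v_exc, params$threshold, params$reset,
                            params$refractory, dt, n, as.numeric(g_exc), v0)
  out <- tibble(time_ms = seq_len(n) * dt, v = res$v)
  attr(out, "spike_times") <- res$spike_times
  attr(out, "rate_hz") <- length(res$spike_times) / duration * 1000
  out
}

#' Closed-form inter-spike interval of the GPe neuron under constant drive
#'
#' For a constant total conductance the integrate-and-fire membrane relaxes
#' exponentially toward the conductance-weighted equilibrium; when that
#' equilibrium exceeds threshold the neuron fires periodically with the
#' analytic crossing time plus the refractory period.
#'
#' @param g_total Constant excitatory conductance (nS).
#' @param params GPe parameters.
#' @return Inter-spike interval (ms), `Inf` when the equilibrium is
#'   subthreshold.
#' @export
gpe_isi_analytic <- function(g_total, params = gpe_params()) {
  p <- params
  gtot <- p$g_leak + g_total
  vinf <- (p$g_leak * p$v_leak + g_total * p$v_exc) / gtot
  if (vinf <= p$threshold) return(Inf)
  tau <- 1000 * p$cm / gtot  # ms
  tau * log((vinf - p$reset) / (vinf - p$threshold)) + p$refractory
}
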