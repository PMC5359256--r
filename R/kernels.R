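# Synaptic conductance kernels: alpha function (cortical AMPA input to STN)
# and beta function, i.e. difference of two exponentials (GABA-A on STN,
# AMPA on GPe).

#' Alpha-function synaptic conductance kernel
#'
#' `g(t) = gmax * (t / tau) * exp(-t / tau)` (as printed form, peaking at
#' `gmax / e`), or scaled so the peak equals `gmax` when
#' `normalize = TRUE` — the convention of common simulator alpha synapses,
#' and the package default throughout the network model.
#'
#' @param t Time since the synaptic event (ms); must be >= 0.
#' @param tau Kernel time constant (ms).
#' @param gmax Maximal conductance (nS).
#' @param normalize Scale the kernel so its peak equals `gmax`.
#' @return Conductance values (nS).
#' @export
alpha_kernel <- function(t, tau = 1, gmax = 1, normalize = TRUE) {
  if (any(t < 0)) abort("alpha kernel is defined for t >= 0")
  if (tau <= 0) abort("tau must be > 0")
  v <- gmax * (t / tau) * exp(-t / tau)
  if (normalize) v * exp(1) else v
}

#' Beta-function (difference of exponentials) conductance kernel
#'
#' `g(t) = k * (exp(-t / tau_decay) - exp(-t / tau_rise))`. With
#' `normalize = FALSE`, `k = gmax` and the realised peak is below `gmax`
#' (the literal printed form); with `normalize = TRUE` (default) the kernel
#' is scaled so its peak equals `gmax`.
#'
#' @param t Time since the synaptic event (ms); must be >= 0.
#' @param tau_rise,tau_decay Rise and decay time constants (ms);
#'   `tau_rise < tau_decay`.
#' @param gmax Maximal conductance (nS).
#' @param normalize Scale so the peak equals `gmax`.
#' @return Conductance values (nS).
#' @export
beta_kernel <- function(t, tau_rise, tau_decay, gmax = 1, normalize = TRUE) {
  if (any(t < 0)) abort("beta kernel is defined for t >= 0")
  if (tau_rise <= 0 || tau_decay <= 0) abort("time constants must be > 0")
  if (tau_rise >= tau_decay) abort("beta kernel requires tau_rise < tau_decay")
  v <- gmax * (exp(-t / tau_decay) - exp(-t / tau_rise))
  if (normalize) v / beta_peak_value(tau_rise, tau_decay) else v
}

#' Peak time of the beta kernel
#'
#' Closed form: `tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @inheritParams beta_kernel
#' @return Peak time (ms).
#' @export
beta_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) abort("beta kernel requires tau_rise < tau_decay")
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# unnormalised peak value of exp(-t/tau_d) - exp(-t/tau_r)
beta_peak_value <- function(tau_rise, tau_decay) {
  tstar <- beta_peak_time(tau_rise, tau_decay)
  exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
}

#' Conductance time course from a spike train by direct kernel summation
#'
#' Brute-force superposition of one kernel per event; the reference against
#' which the engine's state-space kernel realisation is validated.
#'
#' @param spike_times Event times (ms).
#' @param times Evaluation grid (ms).
#' @param kernel Either `"alpha"` or `"beta"`.
#' @param tau Alpha time constant (ms).
#' @param tau_rise,tau_decay Beta time constants (ms).
#' @param gmax Per-event amplitude (nS).
#' @param normalize Peak-normalise each kernel.
#' @return Conductance (nS) at each element of `times`.
#' @export
conductance_from_spikes <- function(spike_times, times, kernel = c("beta", "alpha"),
                                    tau = 1, tau_rise = 0.38, tau_decay = 7.7,
                                    gmax = 1, normalize = TRUE) {
  kernel <- match.arg(kernel)
  out <- numeric(length(times))
  for (s in spike_times) {
    dtv <- times - s
    keep <- dtv >= 0
    if (!any(keep)) next
    out[keep] <- out[keep] + if (kernel == "alpha") {
      alpha_kernel(dtv[keep], tau, gmax, normalize)
    } else {
      beta_kernel(dtv[keep], tau_rise, tau_decay, gmax, normalize)
    }
  }
  out
}
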